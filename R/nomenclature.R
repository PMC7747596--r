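# Shorthand lipid nomenclature: CLASS(c:d), CLASS(c1:d1/c2:d2[/c3:d3]),
# optional _A/_B variant suffix for isobaric analytes with distinct chain sets.

#' Recognized lipid headgroup classes
#'
#' Twelve classes: the plastidic galactolipids and sulfolipid (MGDG, SQDG),
#' phosphoglycerolipids (PC, PE, PI, PA, PG), sterol derivatives (ASG, SG,
#' SE), and the neutral glycerolipids (DAG, TAG).
#'
#' @return Character vector of class tokens.
#' @export
lipid_classes <- function() {
  c("MGDG", "PG", "SQDG", "PC", "PE", "PI", "PA", "ASG", "SG", "SE",
    "DAG", "TAG")
}

#' Diacyl (two-chain) lipid classes
#'
#' @return Character vector of the classes carrying exactly two acyl chains.
#' @export
diacyl_classes <- function() {
  c("DAG", "PC", "PE", "PI", "PA", "PG", "MGDG", "SQDG")
}

# acyl chains per class; the acyl part of ASG/SE is a single chain, the
# sterol glycoside SG carries no acyl chain at all
.chain_count_map <- c(
  MGDG = 2L, PG = 2L, SQDG = 2L, PC = 2L, PE = 2L, PI = 2L, PA = 2L,
  DAG = 2L, TAG = 3L, ASG = 1L, SE = 1L, SG = 0L
)

.parse_chain_tokens <- function(tokens, name) {
  parts <- strsplit(tokens, ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed acyl token in '", name, "'", call. = FALSE)
  }
  carbons <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  double_bonds <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  if (anyNA(carbons) || anyNA(double_bonds)) {
    stop("non-numeric acyl token in '", name, "'", call. = FALSE)
  }
  tibble::tibble(carbons = carbons, double_bonds = double_bonds)
}

.validate_chains <- function(chains, name) {
  if (any(chains$carbons < 2L)) {
    stop("acyl chain with fewer than 2 carbons in '", name, "'",
         call. = FALSE)
  }
  if (any(chains$double_bonds < 0L) ||
      any(chains$double_bonds >= chains$carbons)) {
    stop("double-bond count must be in [0, carbons) in '", name, "'",
         call. = FALSE)
  }
  invisible(chains)
}

.parse_one <- function(name) {
  m <- regmatches(
    name,
    regexec("^([A-Za-z]+)(?:\\(([0-9:/]+)\\))?(?:_([A-Za-z0-9]+))?$", name)
  )[[1]]
  if (length(m) == 0L) {
    stop("cannot parse lipid name '", name, "'", call. = FALSE)
  }
  class <- m[2]
  body <- m[3]
  variant <- if (nzchar(m[4])) m[4] else NA_character_
  if (!class %in% lipid_classes()) {
    stop("unknown lipid class token '", class, "' in '", name, "'",
         call. = FALSE)
  }
  n_chain <- .chain_count_map[[class]]
  if (!nzchar(body)) {
    # only the chain-less sterol glycoside may appear as a bare class token
    if (!identical(class, "SG")) {
      stop("missing (carbons:double bonds) body in '", name, "'",
           call. = FALSE)
    }
    return(list(class = class, total_carbons = 0L, total_double_bonds = 0L,
                chains = NULL, variant = variant))
  }
  tokens <- strsplit(body, "/", fixed = TRUE)[[1]]
  if (length(tokens) > 1L || n_chain == 1L) {
    # explicit chain form (single-chain classes always store their one chain)
    if (length(tokens) != n_chain) {
      stop("'", name, "': ", class, " requires ", n_chain,
           " acyl chain(s), got ", length(tokens), call. = FALSE)
    }
    chains <- .validate_chains(.parse_chain_tokens(tokens, name), name)
    list(class = class,
         total_carbons = sum(chains$carbons),
         total_double_bonds = sum(chains$double_bonds),
         chains = chains, variant = variant)
  } else {
    tot <- .parse_chain_tokens(tokens, name)
    if (tot$carbons < 2L || tot$double_bonds < 0L ||
        tot$double_bonds >= tot$carbons) {
      stop("total double-bond count must be in [0, carbons) in '", name,
           "'", call. = FALSE)
    }
    list(class = class, total_carbons = tot$carbons,
         total_double_bonds = tot$double_bonds, chains = NULL,
         variant = variant)
  }
}

#' Parse shorthand lipid names
#'
#' Accepts the totals form `CLASS(c:d)` (total acyl carbons : total
#' carbon-carbon double bonds), the explicit chain form
#' `CLASS(c1:d1/c2:d2[/c3:d3])`, and an optional `_A`/`_B` suffix
#' distinguishing isobaric analytes with different chain sets.  Chain order
#' carries no sn-position meaning.  For chain-form names the totals are
#' computed from the chains.
#'
#' @param x Character vector of lipid names.
#' @return A tibble with one row per name: `name` (canonical form), `class`,
#'   `total_carbons`, `total_double_bonds`, `chains` (list column of tibbles
#'   with `carbons`, `double_bonds`, or `NULL` when only totals are known),
#'   and `variant`.
#' @examples
#' parse_lipid_name(c("PC(34:3)", "TAG(18:2/16:0/18:1)", "DAG(36:3)_A"))
#' @export
parse_lipid_name <- function(x) {
  stopifnot(is.character(x))
  parsed <- purrr::map(x, .parse_one)
  out <- tibble::tibble(
    class = purrr::map_chr(parsed, "class"),
    total_carbons = purrr::map_int(parsed, "total_carbons"),
    total_double_bonds = purrr::map_int(parsed, "total_double_bonds"),
    chains = purrr::map(parsed, "chains"),
    variant = purrr::map_chr(parsed, "variant")
  )
  out$name <- format_lipid_name(out)
  out[, c("name", "class", "total_carbons", "total_double_bonds",
          "chains", "variant")]
}

#' Format lipid species back to shorthand names
#'
#' Round-trips with [parse_lipid_name()]: formatting a parsed species and
#' re-parsing recovers the same species.
#'
#' @param species A tibble as returned by [parse_lipid_name()] (or a
#'   compatible data frame with `class`, `total_carbons`,
#'   `total_double_bonds`, optional `chains`, `variant`).
#' @return Character vector of canonical names.
#' @export
format_lipid_name <- function(species) {
  species <- tibble::as_tibble(species)
  chains <- if ("chains" %in% names(species)) species$chains else
    vector("list", nrow(species))
  variant <- if ("variant" %in% names(species)) species$variant else
    rep(NA_character_, nrow(species))
  body <- purrr::pmap_chr(
    list(species$class, species$total_carbons, species$total_double_bonds,
         chains),
    function(class, c, d, ch) {
      if (identical(class, "SG") && is.null(ch) && c == 0L) return("SG")
      if (!is.null(ch)) {
        paste0(class, "(",
               paste(ch$carbons, ch$double_bonds, sep = ":", collapse = "/"),
               ")")
      } else {
        paste0(class, "(", c, ":", d, ")")
      }
    }
  )
  ifelse(is.na(variant), body, paste0(body, "_", variant))
}

.as_species <- function(x) {
  if (is.character(x)) parse_lipid_name(x) else tibble::as_tibble(x)
}

#' Number of acyl chains of a lipid species
#'
#' Three for TAG, two for DAG and the diacyl phospho/galactolipids, one for
#' the acyl part of SE and ASG, and zero for SG (no acyl chain).
#'
#' @param x Character vector of lipid names or a parsed species tibble.
#' @return Integer vector.
#' @examples
#' chain_count(c("PC(36:6)", "TAG(52:3)", "SG"))
#' @export
chain_count <- function(x) {
  species <- .as_species(x)
  unname(.chain_count_map[species$class])
}

#' Built-in fatty-acyl assignment map
#'
#' Chain assignments for diacyl species whose fatty-acyl composition is
#' unambiguous, used by the fatty-acid decomposition when a species is named
#' in totals form.  PC: 34:4 = 16:1/18:3, 34:3 = 16:0/18:3, 34:2 = 16:0/18:2,
#' 34:1 = 16:0/18:1, 36:6 = 18:3/18:3, 36:5 = 18:2/18:3, 36:1 = 18:0/18:1;
#' PE: 34:3, 34:2, 34:1, 36:6, 36:5 with the same chain sets.  The 16:0/18:2
#' assignment is used for the 34:2 species: it is the standard-fatty-acid
#' chain pair consistent with the stated totals.  Supply your own map (same
#' columns) to override or extend.
#'
#' @return A tibble with columns `class`, `total_carbons`,
#'   `total_double_bonds`, `chains` (list column).
#' @export
default_fa_assignments <- function() {
  spec <- c(
    "PC" = "34:4=16:1/18:3;34:3=16:0/18:3;34:2=16:0/18:2;34:1=16:0/18:1;36:6=18:3/18:3;36:5=18:2/18:3;36:1=18:0/18:1",
    "PE" = "34:3=16:0/18:3;34:2=16:0/18:2;34:1=16:0/18:1;36:6=18:3/18:3;36:5=18:2/18:3"
  )
  rows <- purrr::imap(spec, function(entries, cls) {
    purrr::map(strsplit(entries, ";", fixed = TRUE)[[1]], function(e) {
      kv <- strsplit(e, "=", fixed = TRUE)[[1]]
      tot <- .parse_chain_tokens(kv[1], kv[1])
      chains <- .parse_chain_tokens(strsplit(kv[2], "/")[[1]], kv[2])
      stopifnot(sum(chains$carbons) == tot$carbons,
                sum(chains$double_bonds) == tot$double_bonds)
      tibble::tibble(class = cls, total_carbons = tot$carbons,
                     total_double_bonds = tot$double_bonds,
                     chains = list(chains))
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

# chains for one species row: explicit chains, else assignment-map lookup,
# else NULL
.species_chains <- function(species_row, assignment) {
  ch <- species_row$chains[[1]]
  if (!is.null(ch)) return(ch)
  hit <- assignment[
    assignment$class == species_row$class &
      assignment$total_carbons == species_row$total_carbons &
      assignment$total_double_bonds == species_row$total_double_bonds, ]
  if (nrow(hit) == 1L) hit$chains[[1]] else NULL
}

#' Occurrences of a fatty acid in a lipid species
#'
#' Counts how many acyl chains of the species equal the given fatty acid.
#' Species named in totals form are resolved through the assignment map; a
#' species with no explicit or assigned chains is ambiguous and raises an
#' error.
#'
#' @param x A single lipid name or one-row parsed species tibble.
#' @param fa Fatty acid as `"carbons:double_bonds"`, e.g. `"18:3"`.
#' @param assignment Assignment map, see [default_fa_assignments()].
#' @return Integer count.
#' @examples
#' fatty_acid_occurrences("PC(36:6)", "18:3")   # 2
#' fatty_acid_occurrences("TAG(18:2/16:0/18:1)", "16:0")
#' @export
fatty_acid_occurrences <- function(x, fa,
                                   assignment = default_fa_assignments()) {
  species <- .as_species(x)
  stopifnot(nrow(species) == 1L)
  target <- .parse_chain_tokens(fa, fa)
  chains <- .species_chains(species[1, ], assignment)
  if (is.null(chains)) {
    stop("fatty-acyl composition of '", species$name[1],
         "' is ambiguous: no explicit chains and no assignment available",
         call. = FALSE)
  }
  sum(chains$carbons == target$carbons &
        chains$double_bonds == target$double_bonds)
}
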