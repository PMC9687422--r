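#' Construct a guild x c-p abundance tally
#'
#' A `guild_cp_tally` is a 4 x 5 non-negative matrix of abundances
#' cross-classified by trophic guild (rows `Ba`, `Fu`, `Pp`, `Op`) and c-p
#' class (columns 1-5). It is the common input to all guild-based indices.
#' Cells are abundances on whatever scale the caller uses (raw counts,
#' densities, or percentages); every index built on a tally is a ratio, so
#' the scale cancels.
#'
#' Cells are named `<guild><cp>` or `<guild>_<cp>`, e.g. `Ba2` or `Ba_2`.
#'
#' @param ... Named cell abundances, e.g. `guild_cp_tally(Ba2 = 10, Op5 = 4)`.
#' @param n_unresolved Abundance of individuals whose genus could not be
#'   resolved to a guild; excluded from guild indices but carried so callers
#'   can account for them.
#' @return A `guild_cp_tally` matrix.
#' @export
guild_cp_tally <- function(..., n_unresolved = 0) {
  cells <- c(...)
  m <- matrix(0, nrow = 4L, ncol = 5L,
              dimnames = list(guild_codes(), as.character(1:5)))
  if (length(cells)) {
    nm <- names(cells)
    if (is.null(nm) || any(!nzchar(nm))) {
      nf_stop("nema_validation_error", "tally cells must be named, e.g. Ba2 = 10")
    }
    parsed <- regmatches(nm, regexec("^(Ba|Fu|Pp|Op)_?([1-5])$", nm))
    ok <- lengths(parsed) == 3L
    if (any(!ok)) {
      nf_stop("nema_validation_error", sprintf(
        "unrecognised tally cell name(s): %s (expected e.g. Ba2, Op_5)",
        paste(nm[!ok], collapse = ", ")
      ))
    }
    for (i in seq_along(cells)) {
      m[parsed[[i]][2], parsed[[i]][3]] <- m[parsed[[i]][2], parsed[[i]][3]] + cells[i]
    }
  }
  new_guild_cp_tally(m, n_unresolved = n_unresolved)
}

new_guild_cp_tally <- function(m, n_unresolved = 0) {
  if (any(m < 0) || n_unresolved < 0) {
    nf_stop("nema_validation_error", "tally abundances must be non-negative")
  }
  structure(m, n_unresolved = as.numeric(n_unresolved),
            class = c("guild_cp_tally", class(matrix())))
}

#' Tally a sample's genus counts by guild and c-p class
#'
#' Each genus contributes its full count to exactly one (guild, c-p) cell,
#' so the tally total equals the sample total.
#'
#' @param counts Named numeric vector of genus counts (names are genus
#'   names), or a `community_sample`-like list with a `counts` element.
#' @param taxonomy A `nema_taxonomy` table.
#' @param unresolved How to treat genera absent from `taxonomy`: `"error"`
#'   (default) signals an unknown-taxon error; `"carry"` accumulates their
#'   counts into the tally's `n_unresolved` attribute.
#' @return A `guild_cp_tally`.
#' @export
tally_guild_cp <- function(counts, taxonomy = default_taxonomy(),
                           unresolved = c("error", "carry")) {
  unresolved <- match.arg(unresolved)
  if (is.list(counts) && !is.null(counts$counts)) counts <- counts$counts
  if (is.null(names(counts)) && length(counts) > 0) {
    nf_stop("nema_validation_error", "counts must be named by genus")
  }
  if (any(counts < 0)) {
    nf_stop("nema_validation_error", "counts must be non-negative")
  }
  m <- matrix(0, nrow = 4L, ncol = 5L,
              dimnames = list(guild_codes(), as.character(1:5)))
  idx <- match(tolower(names(counts)), tolower(taxonomy$genus))
  miss <- is.na(idx)
  if (any(miss) && unresolved == "error") {
    nf_stop("nema_unknown_taxon_error", sprintf(
      "genus not in taxonomy table: %s",
      paste(unique(names(counts)[miss]), collapse = ", ")
    ))
  }
  for (i in which(!miss)) {
    g <- taxonomy$guild[idx[i]]
    k <- taxonomy$cp_value[idx[i]]
    m[g, k] <- m[g, k] + counts[[i]]
  }
  new_guild_cp_tally(m, n_unresolved = sum(counts[miss]))
}

#' Guild marginal abundances of a tally
#'
#' @param tally A `guild_cp_tally`.
#' @return Named numeric vector `Ba`, `Fu`, `Pp`, `Op`.
#' @export
guild_totals <- function(tally) {
  rowSums(unclass(tally))
}

#' Relative abundance of the trophic guilds
#'
#' @param tally A `guild_cp_tally`.
#' @return Named numeric vector of guild percentages summing to 100.
#'   Unresolved individuals are not part of the guild composition.
#' @export
relative_abundance <- function(tally) {
  tot <- guild_totals(tally)
  n <- sum(tot)
  if (n <= 0) {
    nf_undefined("nema_undefined_composition",
                 "relative abundance undefined: no classified individuals")
  }
  100 * tot / n
}

#' @export
print.guild_cp_tally <- function(x, ...) {
  cat("Guild x c-p tally (N =", format(sum(unclass(x))), ")\n")
  print(unclass(x), ...)
  nu <- attr(x, "n_unresolved")
  if (isTRUE(nu > 0)) cat("Unresolved individuals:", format(nu), "\n")
  invisible(x)
}
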