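#' Guild codes recognised by the package
#'
#' Soil nematode genera are classified into four trophic guilds by feeding
#' behaviour: bacterivores (`Ba`), fungivores (`Fu`), plant parasites (`Pp`)
#' and omnivores/predators (`Op`). Carnivorous taxa are folded into `Op`.
#'
#' @return Character vector of the four guild codes.
#' @export
guild_codes <- function() c("Ba", "Fu", "Pp", "Op")

new_taxonomy <- function(df) {
  df$genus <- as.character(df$genus)
  df$guild <- as.character(df$guild)
  df$cp_value <- as.integer(df$cp_value)
  rownames(df) <- NULL
  structure(df, class = c("nema_taxonomy", "data.frame"))
}

validate_taxonomy <- function(df, source = "taxonomy table") {
  bad_guild <- !df$guild %in% guild_codes()
  if (any(bad_guild)) {
    nf_stop("nema_validation_error", sprintf(
      "%s: unknown guild code(s) %s (row %s); expected one of %s",
      source,
      paste(unique(df$guild[bad_guild]), collapse = ", "),
      paste(which(bad_guild), collapse = ", "),
      paste(guild_codes(), collapse = ", ")
    ))
  }
  bad_cp <- is.na(df$cp_value) | df$cp_value < 1 | df$cp_value > 5 |
    df$cp_value != round(df$cp_value)
  if (any(bad_cp)) {
    nf_stop("nema_validation_error", sprintf(
      "%s: c-p value outside 1..5 at row %s",
      source, paste(which(bad_cp), collapse = ", ")
    ))
  }
  dup <- duplicated(tolower(df$genus))
  if (any(dup)) {
    nf_stop("nema_validation_error", sprintf(
      "%s: duplicated genus name(s): %s",
      source, paste(unique(df$genus[dup]), collapse = ", ")
    ))
  }
  invisible(df)
}

#' Read a genus -> guild / c-p reference table
#'
#' The taxonomy file is a UTF-8 CSV with header `genus,guild,cp_value`, one
#' genus per row. Guilds must be one of [guild_codes()]; c-p values are
#' integer life-history scores on the 1-5 colonizer-persister scale
#' (1 = fast-reproducing colonizer, 5 = long-lived persister).
#'
#' @param path Path to the CSV file.
#' @return A `nema_taxonomy` data frame with columns `genus`, `guild`,
#'   `cp_value`.
#' @seealso [default_taxonomy()] for the bundled reference table,
#'   [classify()] for lookups.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) {
    nf_stop("nema_io_error", sprintf("taxonomy file not found: %s", path))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE),
    error = function(e) nf_stop("nema_parse_error", sprintf(
      "cannot parse taxonomy file %s: %s", path, conditionMessage(e)
    ))
  )
  need <- c("genus", "guild", "cp_value")
  if (!all(need %in% names(df))) {
    nf_stop("nema_parse_error", sprintf(
      "taxonomy file %s must have header %s", path, paste(need, collapse = ",")
    ))
  }
  df <- df[, need]
  if (anyNA(df$genus) || any(!nzchar(df$genus))) {
    nf_stop("nema_parse_error", sprintf(
      "taxonomy file %s: empty genus name at line %s",
      path, paste(which(is.na(df$genus) | !nzchar(df$genus)) + 1L, collapse = ", ")
    ))
  }
  cp <- suppressWarnings(as.numeric(df$cp_value))
  if (anyNA(cp)) {
    nf_stop("nema_parse_error", sprintf(
      "taxonomy file %s: non-numeric cp_value at line %s",
      path, paste(which(is.na(cp)) + 1L, collapse = ", ")
    ))
  }
  df$cp_value <- cp
  validate_taxonomy(df, source = sprintf("taxonomy file %s", path))
  new_taxonomy(df)
}

#' Write a taxonomy table to CSV
#'
#' @param taxonomy A `nema_taxonomy` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.csv(as.data.frame(taxonomy), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled default genus -> guild / c-p reference table
#'
#' Ships guild and c-p assignments for the 35 alpine-meadow genera the
#' package's synthetic communities draw from. Guild placements follow
#' standard feeding-group treatments of these taxa; c-p scores are
#' family-level assignments from the canonical colonizer-persister
#' literature. Users with their own assignments should load a custom table
#' with [load_taxonomy()].
#'
#' @return A `nema_taxonomy` data frame.
#' @export
default_taxonomy <- function() {
  load_taxonomy(system.file("extdata", "taxonomy_default.csv",
                            package = "nemafauna", mustWork = TRUE))
}

#' Look up genera in a taxonomy table
#'
#' Matching on genus name is case-insensitive.
#'
#' @param genus Character vector of genus names.
#' @param taxonomy A `nema_taxonomy` table, default [default_taxonomy()].
#' @return The matching rows of `taxonomy`, one per element of `genus`.
#' @export
classify <- function(genus, taxonomy = default_taxonomy()) {
  if (nrow(taxonomy) == 0L) {
    nf_stop("nema_validation_error", "taxonomy table is empty")
  }
  idx <- match(tolower(genus), tolower(taxonomy$genus))
  if (anyNA(idx)) {
    nf_stop("nema_unknown_taxon_error", sprintf(
      "genus not in taxonomy table: %s",
      paste(unique(genus[is.na(idx)]), collapse = ", ")
    ))
  }
  out <- taxonomy[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
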