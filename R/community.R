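#' Ordered depth-layer labels of the sampling design
#'
#' @return Character vector of the five layer labels (cm below surface).
#' @export
depth_layer_labels <- function() c("0-5", "5-10", "10-20", "20-30", "30-40")

#' Assemble a community matrix from count and metadata tables
#'
#' @param counts Long-format data frame with columns `sample_id`, `genus`,
#'   `count` (non-negative integers).
#' @param meta Data frame with columns `sample_id`, `treatment`,
#'   `depth_layer`, `replicate`, `fresh_mass_g`, `water_content` (fraction
#'   in `[0, 1)`).
#' @param taxonomy A `nema_taxonomy` table used to resolve genera.
#' @return A `community_matrix`: list with elements `counts`, `meta`,
#'   `taxonomy` and `unresolved` (genera present in `counts` but absent from
#'   `taxonomy`; these are kept in the data, flagged here, and excluded from
#'   guild-based indices while still counting toward total abundance).
#' @export
community_matrix <- function(counts, meta, taxonomy = default_taxonomy()) {
  need_c <- c("sample_id", "genus", "count")
  need_m <- c("sample_id", "treatment", "depth_layer", "replicate",
              "fresh_mass_g", "water_content")
  if (!all(need_c %in% names(counts))) {
    nf_stop("nema_validation_error", sprintf(
      "counts table must have columns %s", paste(need_c, collapse = ", ")))
  }
  if (!all(need_m %in% names(meta))) {
    nf_stop("nema_validation_error", sprintf(
      "metadata table must have columns %s", paste(need_m, collapse = ", ")))
  }
  counts <- as.data.frame(counts)[, need_c]
  meta <- as.data.frame(meta)[, need_m]
  counts$sample_id <- as.character(counts$sample_id)
  counts$genus <- as.character(counts$genus)
  meta$sample_id <- as.character(meta$sample_id)
  meta$treatment <- as.character(meta$treatment)
  meta$depth_layer <- as.character(meta$depth_layer)

  if (anyDuplicated(meta$sample_id)) {
    nf_stop("nema_validation_error", sprintf(
      "duplicate sample_id in metadata: %s",
      paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", ")))
  }
  if (any(is.na(counts$count) | counts$count < 0 |
          counts$count != round(counts$count))) {
    bad <- which(is.na(counts$count) | counts$count < 0 |
                   counts$count != round(counts$count))
    nf_stop("nema_validation_error", sprintf(
      "counts must be non-negative integers (rows %s)",
      paste(utils::head(bad, 5), collapse = ", ")))
  }
  orphan <- setdiff(unique(counts$sample_id), meta$sample_id)
  if (length(orphan)) {
    nf_stop("nema_linkage_error", sprintf(
      "sample(s) in counts missing from metadata: %s",
      paste(orphan, collapse = ", ")))
  }
  if (any(is.na(meta$fresh_mass_g) | meta$fresh_mass_g <= 0)) {
    nf_stop("nema_validation_error", "fresh_mass_g must be > 0 for every sample")
  }
  if (any(is.na(meta$water_content) | meta$water_content < 0 |
          meta$water_content >= 1)) {
    nf_stop("nema_validation_error",
            "water_content must be a fraction in [0, 1) for every sample")
  }
  unresolved <- sort(unique(counts$genus[
    is.na(match(tolower(counts$genus), tolower(taxonomy$genus)))]))
  if (length(unresolved)) {
    warning(sprintf("genera not in taxonomy (carried as unresolved): %s",
                    paste(unresolved, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(counts = counts, meta = meta, taxonomy = taxonomy,
         unresolved = unresolved),
    class = "community_matrix"
  )
}

#' Read a community matrix from CSV files
#'
#' @param counts_path Long-format counts CSV with header
#'   `sample_id,genus,count`.
#' @param meta_path Metadata CSV with header
#'   `sample_id,treatment,depth_layer,replicate,fresh_mass_g,water_content`.
#' @inheritParams community_matrix
#' @return A `community_matrix`.
#' @export
read_community <- function(counts_path, meta_path, taxonomy = default_taxonomy()) {
  for (p in c(counts_path, meta_path)) {
    if (!file.exists(p)) nf_stop("nema_io_error", sprintf("file not found: %s", p))
  }
  counts <- utils::read.csv(counts_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  community_matrix(counts, meta, taxonomy)
}

#' Write a community matrix to the package's CSV formats
#'
#' @param x A `community_matrix`.
#' @param counts_path,meta_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_community <- function(x, counts_path, meta_path) {
  utils::write.csv(x$counts, counts_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(x$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(counts = counts_path, meta = meta_path))
}

#' Wide genus-by-sample count table
#'
#' Convenience writer/converter: rows are samples, columns genera, missing
#' combinations zero-filled.
#'
#' @param x A `community_matrix`.
#' @return A data frame with `sample_id` plus one column per genus.
#' @export
wide_counts <- function(x) {
  tab <- tapply(x$counts$count,
                list(factor(x$counts$sample_id, levels = x$meta$sample_id),
                     x$counts$genus),
                sum, default = 0)
  out <- data.frame(sample_id = rownames(tab), tab, check.names = FALSE,
                    row.names = NULL)
  out
}

#' Standardize a count to individuals per 100 g dry soil
#'
#' Field counts come from a weighed aliquot of fresh soil; comparisons
#' require a common dry-mass basis. With gravimetric water content `w` the
#' dry mass of the aliquot is `fresh_mass * (1 - w)` on the wet-mass basis
#' (`w = (fresh - dry)/fresh`, the default) or `fresh_mass / (1 + w)` on
#' the dry-mass basis (`w = (fresh - dry)/dry`).
#'
#' @param count Individuals counted (vectorised).
#' @param fresh_mass Fresh soil mass in grams, `> 0`.
#' @param water_content Gravimetric water content as a fraction; `[0, 1)`
#'   for the wet basis, `>= 0` for the dry basis.
#' @param basis `"wet"` (default) or `"dry"`; see Details.
#' @return Individuals per 100 g dry soil.
#' @export
density_per_100g_dry <- function(count, fresh_mass, water_content,
                                 basis = c("wet", "dry")) {
  basis <- match.arg(basis)
  if (any(fresh_mass <= 0)) {
    nf_stop("nema_domain_error", "fresh_mass must be > 0")
  }
  if (any(water_content < 0)) {
    nf_stop("nema_domain_error", "water_content must be non-negative")
  }
  if (basis == "wet" && any(water_content >= 1)) {
    nf_stop("nema_domain_error",
            "wet-basis water_content must be < 1 (all water, no soil)")
  }
  if (any(count < 0)) {
    nf_stop("nema_domain_error", "count must be non-negative")
  }
  dry <- if (basis == "wet") fresh_mass * (1 - water_content)
         else fresh_mass / (1 + water_content)
  count * 100 / dry
}

#' Per-sample genus count vectors
#'
#' @param x A `community_matrix`.
#' @param sample_id One sample id.
#' @return Named numeric vector of genus counts for that sample.
#' @export
sample_counts <- function(x, sample_id) {
  if (!sample_id %in% x$meta$sample_id) {
    nf_stop("nema_linkage_error", sprintf("unknown sample_id: %s", sample_id))
  }
  sub <- x$counts[x$counts$sample_id == sample_id, , drop = FALSE]
  stats::setNames(sub$count, sub$genus)
}

#' Per-sample total densities
#'
#' @param x A `community_matrix`.
#' @param basis Water-content basis, see [density_per_100g_dry()].
#' @return `x$meta` with added columns `n_total` (individuals) and
#'   `density` (ind. per 100 g dry soil).
#' @export
sample_densities <- function(x, basis = "wet") {
  n <- vapply(x$meta$sample_id,
              function(id) sum(x$counts$count[x$counts$sample_id == id]),
              numeric(1))
  out <- x$meta
  out$n_total <- unname(n)
  out$density <- density_per_100g_dry(out$n_total, out$fresh_mass_g,
                                      out$water_content, basis = basis)
  out
}

#' Pool depth layers within each treatment x replicate
#'
#' Sums genus counts across all depth layers of each (treatment, replicate)
#' pair into one 0-40 cm sample; fresh masses are summed and the pooled
#' water content is the mass-weighted mean, so pooled dry mass equals the
#' sum of the layer dry masses. Total individuals are conserved. A
#' replicate missing one or more layers triggers an incomplete-design
#' warning; pooling proceeds over the layers present.
#'
#' @param x A `community_matrix`.
#' @return A `community_matrix` with one sample per (treatment, replicate),
#'   `depth_layer` set to the pooled span.
#' @export
pool_layers <- function(x) {
  meta <- x$meta
  key <- paste(meta$treatment, meta$replicate, sep = "|")
  groups <- split(seq_len(nrow(meta)), key)
  groups <- groups[order(vapply(groups, min, integer(1)))]  # keep input order
  n_layers <- length(unique(meta$depth_layer))
  short <- vapply(groups, function(i) length(i) < n_layers, logical(1))
  if (any(short)) {
    warning(sprintf("incomplete design: %s missing depth layers; pooling present layers",
                    paste(names(groups)[short], collapse = ", ")), call. = FALSE)
  }
  span <- paste(unique(meta$depth_layer), collapse = "+")
  pooled_meta <- do.call(rbind, lapply(names(groups), function(k) {
    i <- groups[[k]]
    fm <- sum(meta$fresh_mass_g[i])
    wc <- sum(meta$fresh_mass_g[i] * meta$water_content[i]) / fm
    data.frame(
      sample_id = paste0(meta$treatment[i[1]], "_r", meta$replicate[i[1]], "_pooled"),
      treatment = meta$treatment[i[1]],
      depth_layer = span,
      replicate = meta$replicate[i[1]],
      fresh_mass_g = fm,
      water_content = wc,
      stringsAsFactors = FALSE
    )
  }))
  id_map <- stats::setNames(rep(names(groups), lengths(groups)),
                            meta$sample_id[unlist(groups)])
  cts <- x$counts
  cts$pool_key <- id_map[cts$sample_id]
  agg <- stats::aggregate(count ~ pool_key + genus, data = cts, FUN = sum)
  key_to_id <- stats::setNames(pooled_meta$sample_id,
                               paste(pooled_meta$treatment, pooled_meta$replicate, sep = "|"))
  pooled_counts <- data.frame(
    sample_id = unname(key_to_id[agg$pool_key]),
    genus = agg$genus,
    count = agg$count,
    stringsAsFactors = FALSE
  )
  pooled_counts <- pooled_counts[order(pooled_counts$sample_id, pooled_counts$genus), ]
  suppressWarnings(community_matrix(pooled_counts, pooled_meta, x$taxonomy))
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("Community matrix: %d samples, %d genera, %d individuals\n",
              nrow(x$meta), length(unique(x$counts$genus)), sum(x$counts$count)))
  cat(sprintf("Treatments: %s\n", paste(unique(x$meta$treatment), collapse = ", ")))
  cat(sprintf("Depth layers: %s\n", paste(unique(x$meta$depth_layer), collapse = ", ")))
  if (length(x$unresolved)) {
    cat("Unresolved genera:", paste(x$unresolved, collapse = ", "), "\n")
  }
  invisible(x)
}
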