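# Per-sample index computation and treatment-level aggregation
# (mean +/- SE over replicates, with LSD compact letters).

index_names <- function() {
  c("H_prime", "J_prime", "lambda_dom", "NCR", "WI", "MI", "PPI", "EI", "SI")
}

# compute one index, converting undefined-value conditions into NA + reason
try_index <- function(expr) {
  tryCatch(list(value = expr, reason = NA_character_),
           nema_undefined = function(e) list(value = NA_real_,
                                             reason = conditionMessage(e)))
}

#' Compute all ecological indices for every sample
#'
#' Diversity indices (`H_prime`, `J_prime`, `lambda_dom`) are computed from
#' the genus counts, including individuals whose genus is not in the
#' taxonomy (they are real individuals). Guild-based indices (`NCR`, `WI`,
#' `MI`, `PPI`, `EI`, `SI`) use the guild x c-p tally of the resolved
#' genera. Mathematically undefined values (e.g. WI with no plant
#' parasites) are recorded as `NA` with the reason retained.
#'
#' @param x A `community_matrix`.
#' @param mode Faunal formula dialect passed to [faunal_components()] and
#'   [ppi()]: `"canonical"` (default) or `"paper_literal"`.
#' @return Data frame with the sample metadata, one column per index, and
#'   attribute `"exclusions"`: a data frame (`sample_id`, `index`,
#'   `reason`) listing every undefined cell.
#' @export
sample_indices <- function(x, mode = c("canonical", "paper_literal")) {
  mode <- match.arg(mode)
  excl <- list()
  rows <- lapply(seq_len(nrow(x$meta)), function(i) {
    sid <- x$meta$sample_id[i]
    cts <- sample_counts(x, sid)
    tly <- tally_guild_cp(cts, x$taxonomy, unresolved = "carry")
    fc_res <- try_index(faunal_components(tly, mode = mode))
    vals <- list(
      H_prime = try_index(shannon(cts)),
      J_prime = try_index(pielou(cts)),
      lambda_dom = try_index(simpson_dominance(cts)),
      NCR = try_index(ncr(tly)),
      WI = try_index(wi(tly)),
      MI = try_index(maturity_index(tly)),
      PPI = try_index(ppi(tly, mode = mode)),
      EI = try_index(enrichment_index(faunal_components(tly, mode = mode))),
      SI = try_index(structure_index(faunal_components(tly, mode = mode)))
    )
    for (nm in names(vals)) {
      if (!is.na(vals[[nm]]$reason)) {
        excl[[length(excl) + 1L]] <<- data.frame(
          sample_id = sid, index = nm, reason = vals[[nm]]$reason,
          stringsAsFactors = FALSE)
      }
    }
    cbind(x$meta[i, , drop = FALSE],
          as.data.frame(lapply(vals, function(v) v$value)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(sample_id = character(), index = character(),
               reason = character(), stringsAsFactors = FALSE)
  out
}

#' Treatment-level index table
#'
#' Computes every index per sample (replicate), then the mean and standard
#' error (sample SD / sqrt(n)) per treatment, with compact significance
#' letters from one-way ANOVA + LSD at level `alpha` where the design
#' permits. Undefined per-sample values are excluded from the mean and the
#' number of defined replicates reported.
#'
#' @inheritParams sample_indices
#' @param alpha Significance level for the LSD letters, default 0.05.
#' @return A `nema_index_table`: list with `per_sample` (see
#'   [sample_indices()]), `per_treatment` (`treatment`, `index`, `mean`,
#'   `se`, `letter`, `n_defined`), `exclusions`, `mode`, `alpha`.
#' @export
index_table <- function(x, mode = c("canonical", "paper_literal"),
                        alpha = 0.05) {
  mode <- match.arg(mode)
  per_sample <- sample_indices(x, mode = mode)
  trts <- unique(x$meta$treatment)
  per_treatment <- do.call(rbind, lapply(index_names(), function(idx) {
    vals <- per_sample[[idx]]
    grp <- per_sample$treatment
    letters_out <- letter_display(vals, grp, trts, alpha)
    do.call(rbind, lapply(trts, function(trt) {
      v <- vals[grp == trt]
      v <- v[!is.na(v)]
      n <- length(v)
      data.frame(
        treatment = trt, index = idx,
        mean = if (n > 0) mean(v) else NA_real_,
        se = if (n > 1) stats::sd(v) / sqrt(n) else NA_real_,
        letter = letters_out[[trt]],
        n_defined = n,
        stringsAsFactors = FALSE)
    }))
  }))
  rownames(per_treatment) <- NULL
  structure(list(per_sample = per_sample, per_treatment = per_treatment,
                 exclusions = attr(per_sample, "exclusions"),
                 mode = mode, alpha = alpha),
            class = "nema_index_table")
}

# letters for one index across treatments; NA where the ANOVA/LSD design
# preconditions fail (e.g. a single replicate, or <2 treatments defined)
letter_display <- function(vals, grp, trts, alpha) {
  out <- stats::setNames(rep(NA_character_, length(trts)), trts)
  keep <- !is.na(vals) & grp %in% trts
  v <- vals[keep]; g <- factor(grp[keep], levels = trts)
  g <- droplevels(g)
  if (nlevels(g) < 2 || length(v) <= nlevels(g)) return(out)
  res <- tryCatch({
    prs <- lsd_pairwise(v, g, alpha = alpha)
    mns <- tapply(v, g, mean)
    compact_letters(stats::setNames(as.numeric(mns), names(mns)), prs)
  }, nemafauna_error = function(e) NULL)
  if (!is.null(res)) out[names(res)] <- res
  out
}

#' @export
print.nema_index_table <- function(x, digits = 2, ...) {
  cat(sprintf("Ecological index table (%s mode, alpha = %g)\n", x$mode, x$alpha))
  wide <- format_index_summary(x, digits = digits)
  print(wide, row.names = FALSE)
  if (nrow(x$exclusions)) {
    cat(sprintf("%d undefined cell(s); see $exclusions\n", nrow(x$exclusions)))
  }
  invisible(x)
}

# mean +/- se + letter, one row per index, one column per treatment
format_index_summary <- function(x, digits = 2) {
  pt <- x$per_treatment
  trts <- unique(pt$treatment)
  out <- data.frame(index = index_names(), stringsAsFactors = FALSE)
  for (trt in trts) {
    col <- vapply(index_names(), function(idx) {
      r <- pt[pt$treatment == trt & pt$index == idx, ]
      if (is.na(r$mean)) return("NA")
      sprintf("%.*f ± %s %s", digits, r$mean,
              if (is.na(r$se)) "NA" else sprintf("%.*f", digits, r$se),
              if (is.na(r$letter)) "" else r$letter)
    }, character(1))
    out[[trt]] <- unname(col)
  }
  out
}

#' Write an index table to CSV
#'
#' Writes the per-sample table and the per-treatment summary
#' (`treatment,index,mean,se,letter,n_defined`), plus the exclusion report
#' if any cell was undefined.
#'
#' @param x A `nema_index_table`.
#' @param per_sample_path,per_treatment_path Output CSV paths.
#' @param exclusions_path Optional path for the exclusion report.
#' @return Invisibly, the paths written.
#' @export
write_index_table <- function(x, per_sample_path, per_treatment_path,
                              exclusions_path = NULL) {
  ps <- x$per_sample
  attr(ps, "exclusions") <- NULL
  utils::write.csv(ps, per_sample_path, row.names = FALSE, na = "NA")
  utils::write.csv(x$per_treatment, per_treatment_path, row.names = FALSE, na = "NA")
  paths <- c(per_sample_path, per_treatment_path)
  if (!is.null(exclusions_path)) {
    utils::write.csv(x$exclusions, exclusions_path, row.names = FALSE)
    paths <- c(paths, exclusions_path)
  }
  invisible(paths)
}
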