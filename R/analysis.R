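#' Faunal analysis of a nematode community experiment
#'
#' The package's central fitting-style entry point: takes a community
#' matrix (field data read with [read_community()] or synthetic data from
#' [generate_dataset()]), optionally pools depth layers within each
#' treatment x replicate, computes the full ecological index suite per
#' replicate, aggregates to treatment means with standard errors and LSD
#' compact letters, and runs the density ANOVAs (one-way per depth layer
#' and, when the design is balanced and complete, the two-factor
#' treatment x layer model).
#'
#' @param x A `community_matrix`.
#' @param mode Faunal formula dialect, `"canonical"` or `"paper_literal"`;
#'   see [faunal_components()].
#' @param alpha Significance level for post hoc letters.
#' @param pool Pool depth layers per replicate before computing indices
#'   (default `TRUE`, matching the convention of computing community
#'   indices on the whole 0-40 cm profile while testing density
#'   layer-by-layer).
#' @param basis Water-content basis for densities, see
#'   [density_per_100g_dry()].
#' @return A `faunal_analysis` object with elements `index_table`
#'   (a [index_table()] result), `densities` (per-sample densities of the
#'   unpooled data), `density_anova` (two-factor `nema_anova` or `NULL` if
#'   the design is not balanced), `mode`, `alpha`, and `call`. Methods:
#'   `print`, `summary`, `coef` (treatment x index mean matrix), `plot`
#'   (EI x SI faunal profile).
#' @examples
#' sim <- generate_dataset(sim_config(rng_seed = 42))
#' fa <- faunal_analysis(sim)
#' fa
#' coef(fa)["CK", "NCR"]
#' @export
faunal_analysis <- function(x, mode = c("canonical", "paper_literal"),
                            alpha = 0.05, pool = TRUE, basis = "wet") {
  mode <- match.arg(mode)
  cl <- match.call()
  dens <- sample_densities(x, basis = basis)
  pooled <- if (pool && length(unique(x$meta$depth_layer)) > 1) pool_layers(x) else x
  it <- index_table(pooled, mode = mode, alpha = alpha)
  density_anova <- tryCatch(
    two_way_anova_balanced(dens$density, dens$treatment, dens$depth_layer),
    nemafauna_error = function(e) NULL)
  structure(list(index_table = it, densities = dens,
                 density_anova = density_anova,
                 mode = mode, alpha = alpha, call = cl),
            class = "faunal_analysis")
}

#' @export
print.faunal_analysis <- function(x, ...) {
  cat("Soil nematode faunal analysis\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Samples: %d (pooled replicates: %d)\n",
              nrow(x$densities), nrow(x$index_table$per_sample)))
  print(x$index_table, ...)
  invisible(x)
}

#' @export
summary.faunal_analysis <- function(object, ...) {
  structure(list(analysis = object), class = "summary.faunal_analysis")
}

#' @export
print.summary.faunal_analysis <- function(x, ...) {
  fa <- x$analysis
  print(fa)
  if (!is.null(fa$density_anova)) {
    cat("\nDensity: treatment x depth-layer ANOVA\n")
    print(fa$density_anova)
  }
  ex <- fa$index_table$exclusions
  if (nrow(ex)) {
    cat("\nUndefined index cells:\n")
    print(ex, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.faunal_analysis <- function(object, ...) {
  pt <- object$index_table$per_treatment
  trts <- unique(pt$treatment)
  m <- matrix(NA_real_, length(trts), length(index_names()),
              dimnames = list(trts, index_names()))
  for (r in seq_len(nrow(pt))) m[pt$treatment[r], pt$index[r]] <- pt$mean[r]
  m
}

#' Faunal profile plot
#'
#' Plots each treatment's mean community on the enrichment (EI) x
#' structure (SI) plane with the conventional 50/50 quadrant split.
#'
#' @param x A `faunal_analysis`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.faunal_analysis <- function(x, ...) {
  m <- coef(x)
  graphics::plot(m[, "SI"], m[, "EI"], xlim = c(0, 100), ylim = c(0, 100),
                 xlab = "Structure index (SI)", ylab = "Enrichment index (EI)",
                 pch = 19, ...)
  graphics::abline(h = 50, v = 50, lty = 2, col = "grey40")
  graphics::text(m[, "SI"], m[, "EI"], rownames(m), pos = 3)
  invisible(x)
}
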