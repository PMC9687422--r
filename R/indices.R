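# Diversity and faunal indices. All take either raw genus counts (diversity)
# or a guild_cp_tally (guild-based indices); every tally-based index is a
# ratio, so the abundance scale cancels.

check_counts <- function(counts) {
  if (any(counts < 0)) nf_stop("nema_validation_error", "counts must be non-negative")
  if (sum(counts) <= 0) {
    nf_undefined("nema_undefined_composition",
                 "index undefined: community has no individuals")
  }
  counts[counts > 0]
}

#' Shannon-Wiener diversity index
#'
#' `H' = -sum p_i ln p_i` over groups with `n_i > 0`, where
#' `p_i = n_i / N`.
#'
#' @param counts Non-negative numeric vector of group abundances.
#' @return `H'` (natural log units).
#' @export
shannon <- function(counts) {
  n <- check_counts(counts)
  p <- n / sum(n)
  -sum(p * log(p))
}

#' Pielou's evenness index
#'
#' `J' = H' / ln S` with `S` the number of groups present (`n_i > 0`).
#' Undefined for a single group (`ln 1 = 0`).
#'
#' @inheritParams shannon
#' @return `J'` in `[0, 1]`.
#' @export
pielou <- function(counts) {
  n <- check_counts(counts)
  s <- length(n)
  if (s < 2) {
    nf_undefined("nema_undefined_evenness",
                 "evenness undefined: fewer than 2 groups present")
  }
  shannon(n) / log(s)
}

#' Simpson dominance index
#'
#' `lambda = sum (n_i / N)^2`. Higher values indicate stronger dominance
#' by few groups (lower diversity).
#'
#' @inheritParams shannon
#' @return `lambda` in `(0, 1]`.
#' @export
simpson_dominance <- function(counts) {
  n <- check_counts(counts)
  p <- n / sum(n)
  sum(p^2)
}

#' Nematode channel ratio
#'
#' `NCR = Ba / (Ba + Fu)`. Values above 0.5 indicate that organic-matter
#' decomposition is dominated by the bacterial channel; below 0.5, the
#' fungal channel.
#'
#' @param tally A `guild_cp_tally`.
#' @return NCR in `[0, 1]`.
#' @export
ncr <- function(tally) {
  g <- guild_totals(tally)
  if (g[["Ba"]] + g[["Fu"]] <= 0) {
    nf_undefined("nema_undefined_channel",
                 "NCR undefined: no bacterivores or fungivores")
  }
  g[["Ba"]] / (g[["Ba"]] + g[["Fu"]])
}

#' Wasilewska index
#'
#' `WI = (Ba + Fu) / Pp`: microbial-feeding relative to plant-feeding
#' nematodes. High values indicate mineralization driven by bacterial- and
#' fungal-feeding taxa; low values, energy flow from plants to herbivores.
#' Undefined (not infinite) when the community has no plant parasites.
#'
#' @param tally A `guild_cp_tally`.
#' @return WI `>= 0`.
#' @export
wi <- function(tally) {
  g <- guild_totals(tally)
  if (g[["Pp"]] <= 0) {
    nf_undefined("nema_undefined_wi", "WI undefined: no plant parasites")
  }
  (g[["Ba"]] + g[["Fu"]]) / g[["Pp"]]
}

#' Maturity index
#'
#' Abundance-weighted mean c-p value of the free-living (non-plant-
#' parasitic) nematodes: `MI = sum_k k * a[g, k] / sum a[g]` over guilds
#' `Ba`, `Fu`, `Op`. Low MI indicates an enriched/disturbed, early-
#' succession community; high MI a structured, late-succession one.
#'
#' @param tally A `guild_cp_tally`.
#' @return MI in `[1, 5]`.
#' @export
maturity_index <- function(tally) {
  m <- unclass(tally)[c("Ba", "Fu", "Op"), , drop = FALSE]
  n <- sum(m)
  if (n <= 0) {
    nf_undefined("nema_undefined_mi", "MI undefined: no free-living individuals")
  }
  sum(sweep(m, 2, 1:5, `*`)) / n
}

#' Plant parasite index
#'
#' The maturity index of the plant-parasitic component. In the default
#' `canonical` mode `PPI = sum_k k * a[Pp, k] / a[Pp]`, keeping PPI on the
#' interpretable 1-5 c-p scale. The `paper_literal` mode divides by the
#' total number of individuals in the whole community instead (some authors
#' describe the proportions that way), which deflates PPI below the c-p
#' scale whenever non-parasites are present.
#'
#' @param tally A `guild_cp_tally`.
#' @param mode `"canonical"` or `"paper_literal"`.
#' @return PPI (`[1, 5]` in canonical mode).
#' @export
ppi <- function(tally, mode = c("canonical", "paper_literal")) {
  mode <- match.arg(mode)
  m <- unclass(tally)
  pp <- m["Pp", ]
  if (sum(pp) <= 0) {
    nf_undefined("nema_undefined_ppi", "PPI undefined: no plant parasites")
  }
  denom <- if (mode == "canonical") sum(pp) else sum(m)
  sum((1:5) * pp) / denom
}

#' Basal, enrichment and structure components of the faunal profile
#'
#' The weighted guild/c-p components underlying the enrichment and
#' structure indices. In the default `canonical` mode the basal component
#' is `b = 0.8 (Ba2 + Fu2)` and the enrichment component
#' `e = 3.2 Ba1 + 0.8 Fu2`, i.e. plant parasites are excluded from the
#' basal/enrichment food web as they are from the maturity index. The
#' `paper_literal` mode substitutes Pp for Ba in those two formulas
#' (`b = 0.8 (Pp2 + Fu2)`, `e = 3.2 Pp1 + 0.8 Fu2`), reproducing the
#' variant occasionally printed in the applied literature. Both modes use
#' `s = sum_{n=3..5} (Ba_n + Fu_n + Op_n) W_n` with weights `W3 = 1.8`,
#' `W4 = 3.2`, `W5 = 5.0`.
#'
#' @param tally A `guild_cp_tally`.
#' @param mode `"canonical"` or `"paper_literal"`.
#' @return A `faunal_components` list with elements `b`, `e`, `s`, `mode`.
#' @export
faunal_components <- function(tally, mode = c("canonical", "paper_literal")) {
  mode <- match.arg(mode)
  m <- unclass(tally)
  basal_guild <- if (mode == "canonical") "Ba" else "Pp"
  b <- 0.8 * (m[basal_guild, "2"] + m["Fu", "2"])
  e <- 3.2 * m[basal_guild, "1"] + 0.8 * m["Fu", "2"]
  w <- c("3" = 1.8, "4" = 3.2, "5" = 5.0)
  s <- sum(colSums(m[c("Ba", "Fu", "Op"), c("3", "4", "5"), drop = FALSE]) * w)
  structure(list(b = b, e = e, s = s, mode = mode),
            class = "faunal_components")
}

#' Enrichment index
#'
#' `EI = 100 e / (e + b)`: responsiveness of the food web to nutrient
#' enrichment.
#'
#' @param fc A `faunal_components` object (or a `guild_cp_tally`, in which
#'   case components are computed in canonical mode).
#' @return EI in `[0, 100]`.
#' @export
enrichment_index <- function(fc) {
  if (inherits(fc, "guild_cp_tally")) fc <- faunal_components(fc)
  if (fc$e + fc$b <= 0) {
    nf_undefined("nema_undefined_ei",
                 "EI undefined: enrichment and basal components both zero")
  }
  # clamp away float round-off so the [0, 100] contract holds exactly
  min(max(100 * fc$e / (fc$e + fc$b), 0), 100)
}

#' Structure index
#'
#' `SI = 100 s / (s + b)`: connectance and food-chain length of the soil
#' food web.
#'
#' @inheritParams enrichment_index
#' @return SI in `[0, 100]`.
#' @export
structure_index <- function(fc) {
  if (inherits(fc, "guild_cp_tally")) fc <- faunal_components(fc)
  if (fc$s + fc$b <= 0) {
    nf_undefined("nema_undefined_si",
                 "SI undefined: structure and basal components both zero")
  }
  min(max(100 * fc$s / (fc$s + fc$b), 0), 100)
}

#' Faunal profile quadrant
#'
#' Joint placement of a community on the enrichment (EI) x structure (SI)
#' plane, split at 50/50: `A` = enriched, unstructured (EI > 50, SI <= 50);
#' `B` = enriched, structured; `C` = structured, resource-limited;
#' `D` = degraded (both <= 50). Boundary values (exactly 50) are assigned
#' to the lower quadrant and flagged via the `"boundary"` attribute.
#'
#' @param ei,si Enrichment and structure index values.
#' @return Character quadrant label with attribute `boundary`.
#' @export
faunal_profile_quadrant <- function(ei, si) {
  if (is.na(ei) || is.na(si)) {
    nf_undefined("nema_undefined_quadrant",
                 "faunal profile undefined: EI or SI undefined")
  }
  q <- if (ei > 50 && si <= 50) "A"
       else if (ei > 50 && si > 50) "B"
       else if (ei <= 50 && si > 50) "C"
       else "D"
  structure(q, boundary = (ei == 50 || si == 50))
}
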