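#' Compact letter display for pairwise comparisons
#'
#' Encodes a set of pairwise significance results as per-group letter
#' strings: two groups share at least one letter if and only if they are
#' not significantly different. Letters are assigned over groups ordered
#' by descending mean (the largest mean receives "a"), via the
#' insert-and-absorb construction: start from a single letter covering all
#' groups, split a letter for each significant pair, and drop letters whose
#' group set is contained in another's. The letter count is deterministic
#' but not guaranteed minimal.
#'
#' @param means Named numeric vector of group means.
#' @param sig_pairs Either a data frame as returned by [lsd_pairwise()]
#'   (columns `group1`, `group2`, `significant`) or a symmetric logical
#'   matrix with group names on both dimensions, `TRUE` marking
#'   significantly different pairs.
#' @return Named character vector of letter strings, in the order of
#'   `means`.
#' @export
compact_letters <- function(means, sig_pairs) {
  gn <- names(means)
  if (is.null(gn)) nf_stop("nema_validation_error", "means must be named")
  if (is.data.frame(sig_pairs)) {
    sig <- matrix(FALSE, length(gn), length(gn), dimnames = list(gn, gn))
    for (r in seq_len(nrow(sig_pairs))) {
      g1 <- sig_pairs$group1[r]; g2 <- sig_pairs$group2[r]
      if (!g1 %in% gn || !g2 %in% gn) {
        nf_stop("nema_validation_error",
                sprintf("pair (%s, %s) not among the named means", g1, g2))
      }
      sig[g1, g2] <- sig[g2, g1] <- isTRUE(sig_pairs$significant[r])
    }
  } else {
    sig <- sig_pairs[gn, gn, drop = FALSE]
  }
  ord <- order(means, decreasing = TRUE)
  groups <- gn[ord]

  # columns = letters; each a character vector of member groups
  cols <- list(groups)
  pair_idx <- which(upper.tri(sig), arr.ind = TRUE)
  # deterministic order: pairs by descending-mean rank
  rank_of <- stats::setNames(seq_along(groups), groups)
  if (nrow(pair_idx)) {
    prs <- data.frame(g1 = rownames(sig)[pair_idx[, 1]],
                      g2 = colnames(sig)[pair_idx[, 2]],
                      stringsAsFactors = FALSE)
    prs <- prs[sig[cbind(prs$g1, prs$g2)], , drop = FALSE]
    if (nrow(prs)) {
      o <- order(pmin(rank_of[prs$g1], rank_of[prs$g2]),
                 pmax(rank_of[prs$g1], rank_of[prs$g2]))
      prs <- prs[o, , drop = FALSE]
      for (r in seq_len(nrow(prs))) {
        g1 <- prs$g1[r]; g2 <- prs$g2[r]
        hit <- which(vapply(cols, function(cl) g1 %in% cl && g2 %in% cl, logical(1)))
        for (ci in hit) {
          cl <- cols[[ci]]
          cols[[ci]] <- setdiff(cl, g1)
          cols[[length(cols) + 1L]] <- setdiff(cl, g2)
        }
        # absorb: drop columns contained in another column
        keep <- rep(TRUE, length(cols))
        for (i in seq_along(cols)) {
          for (j in seq_along(cols)) {
            if (i != j && keep[j] &&
                all(cols[[i]] %in% cols[[j]]) &&
                (length(cols[[i]]) < length(cols[[j]]) || i > j)) {
              keep[i] <- FALSE
              break
            }
          }
        }
        cols <- cols[keep]
      }
    }
  }
  # order letters by the best (smallest) member rank so the top group gets "a"
  best <- vapply(cols, function(cl) min(rank_of[cl]), numeric(1))
  cols <- cols[order(best)]
  out <- stats::setNames(character(length(gn)), gn)
  for (i in seq_along(cols)) {
    out[cols[[i]]] <- paste0(out[cols[[i]]], letters[i])
  }
  out[gn]
}

#' Decode a compact letter display back to a relation
#'
#' Inverse of [compact_letters()] up to the relation it encodes: returns
#' the symmetric logical matrix with `TRUE` where two groups share no
#' letter (i.e. are displayed as significantly different).
#'
#' @param letters_vec Named character vector of letter strings.
#' @return Symmetric logical matrix.
#' @export
decode_letters <- function(letters_vec) {
  gn <- names(letters_vec)
  sets <- lapply(strsplit(letters_vec, ""), unique)
  k <- length(gn)
  m <- matrix(FALSE, k, k, dimnames = list(gn, gn))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) m[i, j] <- length(intersect(sets[[i]], sets[[j]])) == 0
    }
  }
  m
}
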