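# Independent brute-force oracles: explicit loops over individuals/cells,
# written without reference to the package internals.

oracle_shannon <- function(n) {
  n <- n[n > 0]
  p <- n / sum(n)
  h <- 0
  for (pi in p) h <- h - pi * log(pi)
  h
}

oracle_simpson <- function(n) {
  n <- n[n > 0]
  p <- n / sum(n)
  s <- 0
  for (pi in p) s <- s + pi^2
  s
}

# m: plain 4x5 matrix, rows Ba/Fu/Pp/Op, cols c-p 1..5
oracle_guild_sums <- function(m) {
  out <- c(Ba = 0, Fu = 0, Pp = 0, Op = 0)
  for (g in rownames(m)) for (k in 1:5) out[g] <- out[g] + m[g, k]
  out
}

oracle_mi <- function(m) {
  num <- 0; den <- 0
  for (g in c("Ba", "Fu", "Op")) for (k in 1:5) {
    num <- num + k * m[g, k]; den <- den + m[g, k]
  }
  num / den
}

oracle_ppi <- function(m, literal = FALSE) {
  num <- 0
  for (k in 1:5) num <- num + k * m["Pp", k]
  num / if (literal) sum(m) else sum(m["Pp", ])
}

oracle_components <- function(m, literal = FALSE) {
  bg <- if (literal) "Pp" else "Ba"
  b <- 0.8 * (m[bg, 2] + m["Fu", 2])
  e <- 3.2 * m[bg, 1] + 0.8 * m["Fu", 2]
  w <- c(1.8, 3.2, 5.0)
  s <- 0
  for (g in c("Ba", "Fu", "Op")) for (i in 1:3) s <- s + m[g, i + 2] * w[i]
  c(b = b, e = e, s = s)
}

random_tally_matrix <- function() {
  m <- matrix(stats::rpois(20, 2.5), nrow = 4, ncol = 5,
              dimnames = list(c("Ba", "Fu", "Pp", "Op"), as.character(1:5)))
  # sprinkle structural zeros so degenerate branches get exercised too
  m[stats::runif(20) < 0.3] <- 0
  m
}

# a valid treatment x guild proportion matrix for config tests
default_trophic_props_for_test <- function() {
  matrix(rep(c(0.4, 0.15, 0.3, 0.15), each = 5), nrow = 5,
         dimnames = list(c("CK", "A", "B", "C", "D"),
                         c("Ba", "Fu", "Pp", "Op")))
}

# build a guild_cp_tally from a plain matrix through the public constructor
new_tally_for_test <- function(m) {
  cells <- list()
  for (g in rownames(m)) for (k in 1:5) {
    if (m[g, k] != 0) cells[[paste0(g, k)]] <- m[g, k]
  }
  do.call(guild_cp_tally, cells)
}

# small deterministic community used across the data-model tests
make_toy_matrix <- function(taxonomy = default_taxonomy()) {
  counts <- data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s2"),
    genus = c("Acrobeloides", "Rotylenchus", "Aphelenchus",
              "Acrobeloides", "Eudorylaimus", "Rotylenchus"),
    count = c(10L, 5L, 3L, 7L, 4L, 2L),
    stringsAsFactors = FALSE
  )
  meta <- data.frame(
    sample_id = c("s1", "s2"),
    treatment = c("CK", "A"),
    depth_layer = c("0-5", "0-5"),
    replicate = c(1L, 1L),
    fresh_mass_g = c(60, 55),
    water_content = c(0.4, 0.3),
    stringsAsFactors = FALSE
  )
  community_matrix(counts, meta, taxonomy)
}
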