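# Stochastic generator of study-shaped nematode community datasets:
# a warming gradient (5 treatments x 3 replicates x 5 depth layers) with
# surface-aggregated density, treatment-dependent trophic composition and
# treatment-dependent soil moisture. Totals are drawn negative-binomially
# (field nematode counts are overdispersed) and split over genera by a
# guild-then-genus multinomial.

default_trophic_props <- function() {
  rbind(
    CK = c(Ba = 0.4031, Fu = 0.1342, Pp = 0.2872, Op = 0.1755),
    A  = c(Ba = 0.3131, Fu = 0.1000, Pp = 0.3700, Op = 0.2169),
    B  = c(Ba = 0.3380, Fu = 0.0762, Pp = 0.4317, Op = 0.1541),
    C  = c(Ba = 0.3800, Fu = 0.1100, Pp = 0.3300, Op = 0.1800),
    D  = c(Ba = 0.4714, Fu = 0.1491, Pp = 0.1410, Op = 0.2385)
  )
}

default_genus_weights <- function(taxonomy = default_taxonomy()) {
  # heavier weights for the field-dominant genera, uniform elsewhere
  dominant <- c(Acrobeloides = 4, Acrobeles = 3, Cervidellus = 2,
                Rotylenchus = 5, Helicotylenchus = 2, Labronemella = 3,
                Aphelenchus = 3, Eudorylaimus = 2)
  w <- stats::setNames(rep(1, nrow(taxonomy)), taxonomy$genus)
  w[names(dominant)[names(dominant) %in% names(w)]] <-
    dominant[names(dominant) %in% names(w)]
  lapply(stats::setNames(guild_codes(), guild_codes()), function(g) {
    gw <- w[taxonomy$genus[taxonomy$guild == g]]
    gw / sum(gw)
  })
}

#' Configuration for the synthetic community generator
#'
#' Defaults emulate a five-level alpine-meadow warming-gradient design:
#' treatments CK (control) and A-D (increasing warming), 3 replicates,
#' five depth layers with density declining from the surface, trophic
#' composition shifting with warming, and soil water content declining
#' from about 61% (CK) to about 29% (D) on the wet-mass basis.
#'
#' @param treatments Ordered treatment labels.
#' @param n_replicates Replicates per treatment.
#' @param depth_layers Ordered depth-layer labels.
#' @param layer_weights Relative expected density per layer (first layer
#'   = 1); positive, non-increasing by default.
#' @param surface_density Named (per treatment) expected density in the
#'   top layer, individuals per 100 g dry soil.
#' @param trophic_props Treatment x guild matrix of trophic proportions
#'   (rows sum to 1).
#' @param genus_weights Per-guild named lists of within-guild genus
#'   sampling frequencies (each summing to 1).
#' @param water_content_mean Named per-treatment mean gravimetric water
#'   content (wet-mass fraction).
#' @param water_content_sd Per-sample standard deviation of water content.
#' @param fresh_mass_range Range (g) from which fresh aliquot masses are
#'   drawn uniformly.
#' @param nb_size Negative-binomial size (dispersion) parameter for the
#'   per-sample total count; smaller = more overdispersed.
#' @param taxonomy Taxonomy table supplying the genus pool.
#' @param rng_seed Integer seed; identical configurations generate
#'   bit-identical datasets.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(treatments = c("CK", "A", "B", "C", "D"),
                       n_replicates = 3,
                       depth_layers = depth_layer_labels(),
                       layer_weights = c(1, 0.6, 0.35, 0.25, 0.15),
                       surface_density = c(CK = 800, A = 1200, B = 700,
                                           C = 750, D = 650),
                       trophic_props = default_trophic_props(),
                       genus_weights = default_genus_weights(taxonomy),
                       water_content_mean = c(CK = 0.6127, A = 0.55,
                                              B = 0.47, C = 0.38, D = 0.2913),
                       water_content_sd = 0.02,
                       fresh_mass_range = c(50, 70),
                       nb_size = 10,
                       taxonomy = default_taxonomy(),
                       rng_seed = 1L) {
  cfg <- list(treatments = treatments, n_replicates = as.integer(n_replicates),
              depth_layers = depth_layers, layer_weights = layer_weights,
              surface_density = surface_density, trophic_props = trophic_props,
              genus_weights = genus_weights,
              water_content_mean = water_content_mean,
              water_content_sd = water_content_sd,
              fresh_mass_range = fresh_mass_range, nb_size = nb_size,
              taxonomy = taxonomy, rng_seed = as.integer(rng_seed))
  validate_sim_config(cfg)
  cfg$genus_weights <- lapply(cfg$genus_weights, function(w) w / sum(w))
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_replicates < 1) nf_stop("nema_config_error", "n_replicates must be >= 1")
  if (length(cfg$layer_weights) != length(cfg$depth_layers) ||
      any(cfg$layer_weights <= 0)) {
    nf_stop("nema_config_error",
            "layer_weights must be positive, one per depth layer")
  }
  if (!all(cfg$treatments %in% rownames(cfg$trophic_props))) {
    nf_stop("nema_config_error", "trophic_props must have a row per treatment")
  }
  if (!all(guild_codes() %in% colnames(cfg$trophic_props))) {
    nf_stop("nema_config_error", "trophic_props must have columns Ba, Fu, Pp, Op")
  }
  rs <- rowSums(cfg$trophic_props[cfg$treatments, guild_codes(), drop = FALSE])
  if (any(abs(rs - 1) > 1e-9)) {
    nf_stop("nema_config_error", "trophic proportions must sum to 1 per treatment")
  }
  if (any(cfg$trophic_props < 0)) {
    nf_stop("nema_config_error", "trophic proportions must be non-negative")
  }
  if (!all(cfg$treatments %in% names(cfg$surface_density)) ||
      any(cfg$surface_density < 0)) {
    nf_stop("nema_config_error",
            "surface_density must be a non-negative value per treatment")
  }
  if (!all(cfg$treatments %in% names(cfg$water_content_mean)) ||
      any(cfg$water_content_mean < 0) || any(cfg$water_content_mean >= 1)) {
    nf_stop("nema_config_error",
            "water_content_mean must be in [0, 1) per treatment")
  }
  if (length(cfg$fresh_mass_range) != 2 || cfg$fresh_mass_range[1] <= 0 ||
      diff(cfg$fresh_mass_range) < 0) {
    nf_stop("nema_config_error", "fresh_mass_range must be a positive interval")
  }
  if (cfg$nb_size <= 0) nf_stop("nema_config_error", "nb_size must be > 0")
  for (g in guild_codes()) {
    gw <- cfg$genus_weights[[g]]
    # 1e-6 admits weights round-tripped through text config files;
    # they are renormalised exactly in sim_config()
    if (is.null(gw) || length(gw) == 0 || any(gw < 0) ||
        abs(sum(gw) - 1) > 1e-6) {
      nf_stop("nema_config_error", sprintf(
        "genus_weights$%s must be a non-empty probability vector", g))
    }
  }
  invisible(cfg)
}

#' Read / write a simulator configuration file
#'
#' Configurations are stored as YAML (`.yml`/`.yaml`) or JSON; matrices are
#' serialised as named lists. Fields missing from the file fall back to the
#' [sim_config()] defaults.
#'
#' @param path Config file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) nf_stop("nema_io_error", sprintf("config not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- list()
  simple <- c("treatments", "n_replicates", "depth_layers", "layer_weights",
              "water_content_sd", "fresh_mass_range", "nb_size", "rng_seed")
  for (f in simple) if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  for (f in c("surface_density", "water_content_mean")) {
    if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$trophic_props)) {
    tp <- raw$trophic_props
    m <- do.call(rbind, lapply(tp, unlist))
    rownames(m) <- names(tp)
    args$trophic_props <- m
  }
  if (!is.null(raw$genus_weights)) {
    args$genus_weights <- lapply(raw$genus_weights, unlist)
  }
  if (!is.null(raw$taxonomy_path)) args$taxonomy <- load_taxonomy(raw$taxonomy_path)
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @param config A `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  out <- list(
    treatments = config$treatments, n_replicates = config$n_replicates,
    depth_layers = config$depth_layers, layer_weights = config$layer_weights,
    surface_density = as.list(config$surface_density),
    trophic_props = lapply(stats::setNames(config$treatments, config$treatments),
                           function(t) as.list(config$trophic_props[t, guild_codes()])),
    genus_weights = lapply(config$genus_weights, as.list),
    water_content_mean = as.list(config$water_content_mean),
    water_content_sd = config$water_content_sd,
    fresh_mass_range = config$fresh_mass_range,
    nb_size = config$nb_size, rng_seed = config$rng_seed
  )
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path, precision = 15)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Generate a synthetic community dataset
#'
#' Draws one sample per (treatment, replicate, depth layer). For each
#' sample the fresh aliquot mass and water content are drawn, the expected
#' total count is `surface_density * layer_weight * dry_mass / 100`, the
#' realised total is a negative-binomial draw around that expectation, and
#' genus counts are a multinomial split with probabilities
#' `trophic proportion x within-guild genus frequency`. Identical
#' configurations (including `rng_seed`) yield bit-identical datasets.
#'
#' @param config A `sim_config`.
#' @param seed Optional seed overriding `config$rng_seed`.
#' @return A `community_matrix`.
#' @export
generate_dataset <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  seed <- as.integer(seed %||% config$rng_seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  genus_p <- function(trt) {
    props <- config$trophic_props[trt, guild_codes()]
    unlist(lapply(guild_codes(), function(g) props[[g]] * config$genus_weights[[g]]))
  }

  meta_rows <- list(); count_rows <- list()
  for (trt in config$treatments) {
    p_genus <- genus_p(trt)
    for (rep_i in seq_len(config$n_replicates)) {
      for (li in seq_along(config$depth_layers)) {
        fm <- stats::runif(1, config$fresh_mass_range[1], config$fresh_mass_range[2])
        wc <- stats::rnorm(1, config$water_content_mean[[trt]], config$water_content_sd)
        wc <- min(max(wc, 0), 0.95)
        dry <- fm * (1 - wc)
        mu <- config$surface_density[[trt]] * config$layer_weights[li] * dry / 100
        total <- stats::rnbinom(1, size = config$nb_size, mu = mu)
        sid <- sprintf("%s_r%d_L%d", trt, rep_i, li)
        meta_rows[[sid]] <- data.frame(
          sample_id = sid, treatment = trt,
          depth_layer = config$depth_layers[li], replicate = rep_i,
          fresh_mass_g = round(fm, 2), water_content = round(wc, 4),
          stringsAsFactors = FALSE)
        if (total > 0) {
          draws <- stats::rmultinom(1, total, prob = p_genus)[, 1]
          nz <- draws > 0
          if (any(nz)) {
            count_rows[[sid]] <- data.frame(
              sample_id = sid, genus = names(draws)[nz],
              count = unname(draws[nz]), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  meta <- do.call(rbind, meta_rows); rownames(meta) <- NULL
  counts <- if (length(count_rows)) do.call(rbind, count_rows) else
    data.frame(sample_id = character(), genus = character(),
               count = integer(), stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  community_matrix(counts, meta, config$taxonomy)
}

#' Recover generating parameters from a synthetic dataset
#'
#' Validation harness for the generator: estimates the depth-decay profile
#' (normalised mean density per layer) and the per-treatment trophic
#' proportions, each with standard errors, for comparison with the
#' generating configuration.
#'
#' @param x A `community_matrix`.
#' @param basis Water-content basis for densities.
#' @return List with data frames `layer_profile` (`depth_layer`, `weight`,
#'   `se`) and `trophic` (`treatment`, `guild`, `proportion`, `se`).
#' @export
recover_parameters <- function(x, basis = "wet") {
  if (nrow(x$meta) == 0) nf_stop("nema_design_error", "empty community matrix")
  dens <- sample_densities(x, basis = basis)
  layer_means <- tapply(dens$density, dens$depth_layer, mean)
  layer_se <- tapply(dens$density, dens$depth_layer,
                     function(v) stats::sd(v) / sqrt(length(v)))
  # keep the input layer order
  lv <- unique(x$meta$depth_layer)
  layer_means <- layer_means[lv]; layer_se <- layer_se[lv]
  top <- layer_means[[1]]
  layer_profile <- data.frame(depth_layer = lv,
                              weight = as.numeric(layer_means / top),
                              se = as.numeric(layer_se / top),
                              stringsAsFactors = FALSE)
  trts <- unique(x$meta$treatment)
  trophic <- do.call(rbind, lapply(trts, function(trt) {
    ids <- x$meta$sample_id[x$meta$treatment == trt]
    cts <- x$counts[x$counts$sample_id %in% ids, , drop = FALSE]
    total <- stats::setNames(tapply(cts$count, cts$genus, sum),
                             names(tapply(cts$count, cts$genus, sum)))
    tly <- tally_guild_cp(total, x$taxonomy, unresolved = "carry")
    g <- guild_totals(tly); n <- sum(g)
    p <- if (n > 0) g / n else rep(NA_real_, 4)
    data.frame(treatment = trt, guild = names(g), proportion = as.numeric(p),
               se = as.numeric(sqrt(p * (1 - p) / n)),
               stringsAsFactors = FALSE)
  }))
  rownames(trophic) <- NULL
  list(layer_profile = layer_profile, trophic = trophic)
}
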