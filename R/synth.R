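# Seeded synthetic generators: trait databases, modern-survey model datasets,
# and archaeobotanical count matrices with known group structure. These
# emulate the statistical shape of the real inputs (trait ranges, two-group
# field surveys, sparse seed-count matrices) so the whole pipeline is testable
# offline; they make no attempt at ecological realism.

# baseline (grand-mean) trait values shared by the species and field
# generators; scales follow the trait definitions: SLA mm^2/mg, ARNODE
# mm^2/mm, canopy sizes log10 cm, FLOWPER months, VEGPROP a 0/1 proportion
.synth_baseline <- c(SLA = 22, ARNODE = 30, LOGCANH = 1.5, LOGCAND = 1.3,
                     VEGPROP = 0.4, FLOWPER = 4.5)
# species-level spread (between-species SD) on the same scales
.synth_species_sd <- c(SLA = 6, ARNODE = 10, LOGCANH = 0.3, LOGCAND = 0.3,
                       VEGPROP = 0.49, FLOWPER = 2.0)
# field-level (within-group, between-field) SD — fields average many species,
# so their spread is smaller than the species spread
.synth_field_sd <- c(SLA = 3, ARNODE = 5, LOGCANH = 0.15, LOGCAND = 0.15,
                     VEGPROP = 0.12, FLOWPER = 0.8)
# default group separation (group 1 minus group 2) per predictor: group 1 is
# the high-input / high-disturbance regime, hence larger leaves, taller and
# wider canopies, longer flowering, more vegetative propagation
.synth_shift <- c(SLA = 6, ARNODE = 8, LOGCANH = 0.25, LOGCAND = 0.2,
                  VEGPROP = 0.25, FLOWPER = 1.5)

#' Configuration for the synthetic data generators
#'
#' Bundles every tunable of the generators with documented defaults sized for
#' quick desk-scale runs. `group_mean_shift` is the difference between the two
#' regimes' field-level trait means (group 1 minus group 2) on each
#' predictor's own scale; `within_group_cov` is the field-level covariance
#' shared by both groups (default: diagonal with realistic per-trait SDs).
#'
#' @param seed Integer seed; every generator draw flows from it.
#' @param n_species Number of species in the synthetic trait database.
#' @param n_fields_per_group Modern survey fields per regime group.
#' @param n_samples Archaeobotanical samples in the synthetic count matrix.
#' @param group_mean_shift Named numeric vector of per-predictor group-mean
#'   differences (any subset of the six traits; omitted traits shift by 0).
#' @param within_group_cov Field-level covariance matrix (named dims), or
#'   `NULL` for the default diagonal.
#' @param species_per_sample Integer range `c(min, max)` of species per
#'   archaeobotanical sample.
#' @param seeds_per_species Mean of the (shifted) Poisson seed count drawn for
#'   each present species: counts are `1 + rpois(mean - 1)`.
#' @param missing_vegprop_rate Fraction of species with VEGPROP unrecorded.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_species = 60L, n_fields_per_group = 20L,
                         n_samples = 50L,
                         group_mean_shift = .synth_shift,
                         within_group_cov = NULL,
                         species_per_sample = c(5L, 15L),
                         seeds_per_species = 8,
                         missing_vegprop_rate = 0.1) {
  shift <- .synth_shift * 0
  shift[names(group_mean_shift)] <- group_mean_shift
  if (is.null(within_group_cov))
    within_group_cov <- diag(.synth_field_sd^2)
  dimnames(within_group_cov) <- list(names(.synth_field_sd),
                                     names(.synth_field_sd))
  ev <- eigen(within_group_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop("within_group_cov must be positive-definite", call. = FALSE)
  if (missing_vegprop_rate < 0 || missing_vegprop_rate > 1)
    stop("missing_vegprop_rate must lie in [0, 1]", call. = FALSE)
  if (n_species < 2L) stop("n_species must be >= 2", call. = FALSE)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 n_fields_per_group = as.integer(n_fields_per_group),
                 n_samples = as.integer(n_samples),
                 group_mean_shift = shift,
                 within_group_cov = within_group_cov,
                 species_per_sample = as.integer(species_per_sample),
                 seeds_per_species = seeds_per_species,
                 missing_vegprop_rate = missing_vegprop_rate),
            class = "synth_config")
}

# deterministic sub-seed so the three generators are independent of each
# other's draw counts; kept below 2^31
.sub_seed <- function(config, offset) (config$seed * 97L + offset) %% 2147483587L

# invent a pronounceable fake latin binomial
.fake_name <- function(min_syl = 2L, max_syl = 4L) {
  cons <- c("b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v")
  vow <- c("a", "e", "i", "o", "u")
  n <- sample(min_syl:max_syl, 1L)
  paste0(paste0(sample(cons, n, TRUE), sample(vow, n, TRUE), collapse = ""),
         sample(c("", "um", "is", "a"), 1L))
}

#' Generate a synthetic trait database
#'
#' Species codes are derived from invented binomials via [make_species_code()]
#' (collisions resolved sequentially, so the code scheme gets exercised).
#' Trait values are drawn around realistic baselines: SLA and ARNODE strictly
#' positive, canopy sizes on the log scale, VEGPROP Bernoulli with the
#' configured missing rate, FLOWPER uniform on 1–8 months.
#'
#' @param config A [synth_config].
#' @return A [trait_db] (version string identifies it as synthetic).
#' @export
make_trait_db <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(.sub_seed(config, 1L))
  n <- config$n_species
  codes <- character(n); genus <- character(n); epithet <- character(n)
  for (i in seq_len(n)) {
    repeat {
      g <- .fake_name(); e <- .fake_name()
      cd <- tryCatch(make_species_code(g, e, codes[seq_len(i - 1L)]),
                     error = function(err) NA_character_)
      if (!is.na(cd)) break
    }
    codes[i] <- cd; genus[i] <- g; epithet[i] <- e
  }
  b <- .synth_baseline; s <- .synth_species_sd
  sla <- pmax(stats::rnorm(n, b["SLA"], s["SLA"]), 2)
  arn <- pmax(stats::rnorm(n, b["ARNODE"], s["ARNODE"]), 2)
  vp <- stats::rbinom(n, 1L, b["VEGPROP"])
  vp[stats::runif(n) < config$missing_vegprop_rate] <- NA
  records <- data.frame(
    code = codes, genus = genus, epithet = epithet,
    SLA = sla, ARNODE = arn,
    LOGCANH = stats::rnorm(n, b["LOGCANH"], s["LOGCANH"]),
    LOGCAND = stats::rnorm(n, b["LOGCAND"], s["LOGCAND"]),
    VEGPROP = vp,
    LIFEHIST = sample(c("annual", "perennial", "other"), n, TRUE,
                      prob = c(0.6, 0.35, 0.05)),
    FLOWPER = sample(1:8, n, TRUE),
    stringsAsFactors = FALSE)
  trait_db(records, version = paste0("synthetic-", config$seed))
}

#' Generate a synthetic modern-survey model dataset
#'
#' Draws `n_fields_per_group` field-level trait vectors per regime group from
#' two Gaussians sharing `within_group_cov`, with means separated by
#' `group_mean_shift` and centred on the generator baseline. Groups get two
#' location labels each for models 2 and 3 (which pool several survey
#' regions), one each for model 1.
#'
#' @param config A [synth_config].
#' @param model_id Model id (1, 2 or 3) selecting the predictor subset.
#' @return A `weed_model_data` data frame (see [as_model_data()]).
#' @export
make_model_data <- function(config, model_id) {
  stopifnot(inherits(config, "synth_config"))
  predictors <- weed_predictors(model_id)
  set.seed(.sub_seed(config, 2L + as.integer(model_id)))
  n <- config$n_fields_per_group
  mu0 <- .synth_baseline[predictors]
  shift <- config$group_mean_shift[predictors]
  S <- config$within_group_cov[predictors, predictors, drop = FALSE]
  R <- chol(S)
  draw <- function(mu, n) {
    Z <- matrix(stats::rnorm(n * length(mu)), n)
    sweep(Z %*% R, 2L, mu, "+")
  }
  X <- rbind(draw(mu0 + shift / 2, n), draw(mu0 - shift / 2, n))
  colnames(X) <- predictors
  locs <- if (model_id == 1L) c("alpha", "beta") else
    c("alpha", "gamma", "beta", "delta")
  loc <- if (model_id == 1L) {
    rep(locs, each = n)
  } else {
    c(rep(locs[1:2], length.out = n), rep(locs[3:4], length.out = n))
  }
  df <- data.frame(group = rep(c(1L, 2L), each = n), location = loc, X,
                   stringsAsFactors = FALSE)
  as_model_data(df, model_id)
}

#' Generate a synthetic archaeobotanical count matrix
#'
#' Each sample is assigned to a regime group and draws its species with
#' inclusion probabilities tilted toward that group: a species' standardised
#' trait values are projected onto the configured group-shift direction and
#' passed through a logistic link, so samples from group 1 preferentially
#' contain species whose traits resemble the group 1 field mean. Seed counts
#' per present species are `1 + Poisson(seeds_per_species - 1)`. The
#' configured minimum species per sample is guaranteed.
#'
#' @param config A [synth_config].
#' @param db A [trait_db], typically from [make_trait_db()].
#' @param group_assignment Integer vector (values 1/2) of length `n_samples`,
#'   or a single value recycled; the known ground truth.
#' @param tilt Strength of the logistic tilt (0 = no group signal).
#' @return Numeric taxa-by-samples matrix with attribute `"group"` holding the
#'   ground-truth assignment.
#' @export
make_counts <- function(config, db, group_assignment = 1L, tilt = 2) {
  stopifnot(inherits(config, "synth_config"), inherits(db, "trait_db"))
  set.seed(.sub_seed(config, 11L))
  ns <- config$n_samples
  grp <- as.integer(rep_len(group_assignment, ns))
  stopifnot(all(grp %in% c(1L, 2L)))

  traits <- intersect(names(.synth_baseline), names(db$records))
  Z <- as.matrix(db$records[, traits, drop = FALSE])
  Z <- sweep(sweep(Z, 2L, .synth_baseline[traits], "-"), 2L,
             .synth_species_sd[traits], "/")
  Z[is.na(Z)] <- 0
  # project standardised species traits onto the group-shift direction
  u <- config$group_mean_shift[traits] / .synth_species_sd[traits]
  u <- if (sum(u^2) > 0) u / sqrt(sum(u^2)) else u
  score <- drop(Z %*% u)

  nsp <- nrow(db$records)
  rng <- config$species_per_sample
  m <- matrix(0, nrow = nsp, ncol = ns,
              dimnames = list(db$records$code,
                              sprintf("S%03d", seq_len(ns))))
  for (j in seq_len(ns)) {
    side <- if (grp[j] == 1L) 1 else -1
    k <- sample(rng[1L]:rng[2L], 1L)
    w <- stats::plogis(tilt * side * score)
    picked <- sample.int(nsp, size = min(k, nsp), prob = w)
    m[picked, j] <- 1 + stats::rpois(length(picked),
                                     max(config$seeds_per_species - 1, 0))
  }
  attr(m, "group") <- grp
  m
}

#' Write a full synthetic fixture set
#'
#' Convenience wrapper for the `simulate` CLI subcommand: writes `db.csv`,
#' `model_data.csv`, `counts.csv` and `flowper.csv` for one model preset into
#' a directory.
#'
#' @param config A [synth_config].
#' @param model_id Model id for the survey dataset.
#' @param dir Output directory (created if needed).
#' @param group_assignment Ground-truth regime per sample (recycled).
#' @return Invisibly, named vector of the paths written.
#' @export
write_synth_fixtures <- function(config, model_id, dir,
                                 group_assignment = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  db <- make_trait_db(config)
  md <- make_model_data(config, model_id)
  counts <- make_counts(config, db, group_assignment)
  paths <- c(db = file.path(dir, "db.csv"),
             model_data = file.path(dir, "model_data.csv"),
             counts = file.path(dir, "counts.csv"),
             flowper = file.path(dir, "flowper.csv"))
  write_trait_csv(db, paths["db"])
  utils::write.csv(as.data.frame(md), paths["model_data"],
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(species.codes = rownames(counts), counts,
                              check.names = FALSE),
                   paths["counts"], row.names = FALSE, quote = FALSE)
  write_flowper_csv(stats::setNames(db$records$FLOWPER, db$records$code),
                    paths["flowper"])
  invisible(paths)
}
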