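# Synthetic cohort generator.
#
# Emulates the statistical structure a metabolome-phenome scan assumes:
# a positive, right-skewed (log-normal) correlated metabolite panel with
# lipid-like block correlation, stylized baseline covariates, disease
# endpoints generated under known odds/hazard ratios or known pre-onset
# divergence profiles, traits with known linear/logistic/ordinal links,
# and nonlinear metabolite age-"waves" with known crest ages. Every
# planted parameter is recorded in the bundle's ground truth.

#' Disease specification for the synthetic registry
#'
#' @param disease_id unique identifier string.
#' @param mode `"hazard_driven"` (exponential proportional hazards on
#'   planted log-HRs), `"divergence_driven"` (cases' baseline metabolite
#'   levels shifted as a known function of time-to-onset), or `"null"`
#'   (outcomes independent of metabolites).
#' @param prevalence_prevalent baseline-prevalent probability in (0, 1).
#' @param incidence_scale baseline hazard (events per person-year).
#' @param effect_metabolites two-column matrix or data.frame
#'   (`metabolite` 1-based index, `effect` log-HR and log-OR per SD);
#'   `NULL` for none.
#' @param divergence for `divergence_driven` only: list with `metabolite`
#'   (index), `emergence_time` (years before onset at which divergence
#'   begins), `shift` (SD units reached at onset) and `ramp`
#'   (`"linear"` or `"step"`).
#' @return a `disease_spec` list.
#' @export
disease_spec <- function(disease_id, mode = c("hazard_driven", "divergence_driven", "null"),
                         prevalence_prevalent = 0.05, incidence_scale = 0.002,
                         effect_metabolites = NULL, divergence = NULL) {
  mode <- match.arg(mode)
  assert_prob(prevalence_prevalent, "prevalence_prevalent")
  if (incidence_scale < 0) stop("incidence_scale must be >= 0")
  if (mode == "divergence_driven" && is.null(divergence))
    stop("divergence spec required when mode = 'divergence_driven'")
  if (mode != "divergence_driven" && !is.null(divergence))
    stop("divergence spec only allowed when mode = 'divergence_driven'")
  if (!is.null(divergence)) {
    stopifnot(all(c("metabolite", "emergence_time", "shift") %in% names(divergence)))
    divergence$ramp <- match.arg(divergence$ramp %||% "linear", c("linear", "step"))
    if (divergence$emergence_time <= 0) stop("emergence_time must be > 0")
  }
  if (!is.null(effect_metabolites)) {
    effect_metabolites <- as.data.frame(effect_metabolites)
    names(effect_metabolites) <- c("metabolite", "effect")
  }
  structure(list(disease_id = disease_id, mode = mode,
                 prevalence_prevalent = prevalence_prevalent,
                 incidence_scale = incidence_scale,
                 effect_metabolites = effect_metabolites,
                 divergence = divergence),
            class = "disease_spec")
}

#' Trait specification for the synthetic cohort
#'
#' @param trait_id unique identifier string.
#' @param kind `"continuous"`, `"ordinal"` or `"binary"`.
#' @param effect_metabolites two-column matrix/data.frame
#'   (`metabolite` index, `effect` per SD); `NULL` for a pure-noise trait.
#' @param n_ordinal_levels number of ordered levels (ordinal only, >= 3).
#' @param noise_sd residual SD (continuous) / latent noise SD (ordinal).
#' @param intercept linear-predictor intercept; for binary traits this
#'   sets the implied prevalence via `plogis(intercept)`.
#' @return a `trait_spec` list.
#' @export
trait_spec <- function(trait_id, kind = c("continuous", "ordinal", "binary"),
                       effect_metabolites = NULL, n_ordinal_levels = 4L,
                       noise_sd = 1, intercept = 0) {
  kind <- match.arg(kind)
  if (kind == "ordinal" && n_ordinal_levels < 3L) stop("ordinal traits need >= 3 levels")
  if (!is.null(effect_metabolites)) {
    effect_metabolites <- as.data.frame(effect_metabolites)
    names(effect_metabolites) <- c("metabolite", "effect")
  }
  structure(list(trait_id = trait_id, kind = kind,
                 effect_metabolites = effect_metabolites,
                 n_ordinal_levels = as.integer(n_ordinal_levels),
                 noise_sd = noise_sd, intercept = intercept),
            class = "trait_spec")
}

#' Build and validate a simulation configuration
#'
#' Defaults describe a stylized mid-life population cohort: ages uniform
#' on 40-70 years, 54% female, predominantly one ethnic group, 22
#' assessment centres of unequal size, and a 313-column log-normal
#' metabolite panel with block correlation. The defaults are stylized,
#' not estimates of any real cohort's joint distribution.
#'
#' @param n_participants cohort size.
#' @param n_metabolites number of metabolite columns (default 313).
#' @param blocks list of `c(size, rho)` pairs giving correlated blocks on
#'   the latent Gaussian scale; remaining metabolites are independent.
#' @param diseases list of [disease_spec()] objects.
#' @param traits list of [trait_spec()] objects.
#' @param waves list of `list(metabolite, crest_age, amplitude, width)`
#'   planted sigmoidal age-waves: the metabolite's latent mean follows
#'   `amplitude * plogis((age - crest_age) / width)` so the transition is
#'   centred (steepest) at the crest age. `width` in years (default 1).
#' @param age_slopes optional per-metabolite linear age slope on the
#'   latent scale (SD units per year); default all zero.
#' @param log_scale_sd log-scale SD mapping the unit-variance latent
#'   Gaussian to the raw concentration scale, `raw = exp(log_scale_sd *
#'   latent)`; default 0.3 (a ~30% coefficient of variation, typical of
#'   circulating metabolite panels). Planted effects, waves and
#'   divergences are all expressed in latent SD units and are unaffected
#'   by this choice after the QC z-transform.
#' @param follow_up_horizon follow-up length in years (default 15).
#' @param n_centres number of assessment centres (default 22).
#' @param missingness per-covariate missingness proportion injected into
#'   ethnicity/TDI/BMI/smoking/statin/fasting (never sex, age, centre or
#'   metabolites); default 0.02.
#' @param include_egfr add an eGFR covariate column.
#' @param seed integer seed; the whole bundle is deterministic given it.
#' @return a validated `sim_config` list.
#' @export
simulation_config <- function(n_participants, n_metabolites = 313L,
                              blocks = list(), diseases = list(), traits = list(),
                              waves = list(), age_slopes = NULL,
                              log_scale_sd = 0.3,
                              follow_up_horizon = 15, n_centres = 22L,
                              missingness = 0.02, include_egfr = FALSE, seed = 1L) {
  stopifnot(n_participants >= 2, n_metabolites >= 1, follow_up_horizon > 0,
            missingness >= 0, missingness < 1, log_scale_sd > 0)
  if (length(blocks)) {
    sizes <- vapply(blocks, function(b) b[[1L]], numeric(1))
    rhos <- vapply(blocks, function(b) b[[2L]], numeric(1))
    if (any(rhos < -1 | rhos > 1)) stop("block correlations must lie in [-1, 1]")
    if (sum(sizes) > n_metabolites) stop("block sizes sum beyond n_metabolites")
  }
  ids <- vapply(diseases, function(d) d$disease_id, character(1))
  if (anyDuplicated(ids)) stop("disease_id collision: ", ids[duplicated(ids)][1L])
  tids <- vapply(traits, function(t) t$trait_id, character(1))
  if (anyDuplicated(tids)) stop("trait_id collision: ", tids[duplicated(tids)][1L])
  for (d in diseases) {
    if (!is.null(d$divergence) && d$divergence$emergence_time > follow_up_horizon)
      stop("emergence_time must lie in (0, follow_up_horizon]")
  }
  for (w in waves) {
    stopifnot(w$metabolite >= 1, w$metabolite <= n_metabolites)
    w$width <- w$width %||% 1
  }
  if (!is.null(age_slopes)) stopifnot(length(age_slopes) == n_metabolites)
  structure(list(n_participants = as.integer(n_participants),
                 n_metabolites = as.integer(n_metabolites),
                 blocks = blocks, diseases = diseases, traits = traits,
                 waves = waves, age_slopes = age_slopes,
                 log_scale_sd = log_scale_sd,
                 follow_up_horizon = follow_up_horizon,
                 n_centres = as.integer(n_centres),
                 missingness = missingness, include_egfr = include_egfr,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# latent-scale planted mean for metabolite j at given ages
planted_age_mean <- function(config, j, ages) {
  mu <- rep(0, length(ages))
  if (!is.null(config$age_slopes)) mu <- mu + config$age_slopes[j] * (ages - 55)
  for (w in config$waves) {
    if (w$metabolite == j)
      mu <- mu + w$amplitude * stats::plogis((ages - w$crest_age) / (w$width %||% 1))
  }
  mu
}

# assemble block-diagonal latent correlation and draw n x p latent normals
draw_latent <- function(n, p, blocks) {
  z <- matrix(rnorm(n * p), n, p)
  pos <- 1L
  for (b in blocks) {
    size <- as.integer(b[[1L]]); rho <- b[[2L]]
    idx <- pos:(pos + size - 1L)
    if (size > 1L && rho != 0) {
      R <- matrix(rho, size, size); diag(R) <- 1
      ch <- tryCatch(chol(R), error = function(e)
        stop("invalid correlation matrix: block of size ", size,
             " with rho ", rho, " is not positive definite", call. = FALSE))
      z[, idx] <- z[, idx] %*% ch
    }
    pos <- pos + size
  }
  z
}

gen_covariates <- function(config) {
  n <- config$n_participants
  centre_w <- exp(seq(0, 1.5, length.out = config$n_centres))
  df <- data.frame(
    id = sprintf("P%07d", seq_len(n)),
    age = runif(n, 40, 70),
    sex = ifelse(runif(n) < 0.54, "Female", "Male"),
    ethnicity = sample(c("group_A", "group_B", "group_C"), n, TRUE, c(0.95, 0.03, 0.02)),
    tdi = rnorm(n, 0, 3),
    bmi = rnorm(n, 27.4, 4.8),
    smoking = sample(c("never", "former", "current"), n, TRUE, c(0.55, 0.35, 0.10)),
    statin = rbinom(n, 1L, 0.17),
    fasting = pmax(0.5, rgamma(n, shape = 4, rate = 1)),
    centre = sample(sprintf("centre_%02d", seq_len(config$n_centres)), n, TRUE,
                    centre_w / sum(centre_w)),
    stringsAsFactors = FALSE
  )
  if (config$include_egfr) df$egfr <- rnorm(n, 90, 13)
  if (config$missingness > 0) {
    for (cv in intersect(c("ethnicity", "tdi", "bmi", "smoking", "statin", "fasting", "egfr"),
                         names(df))) {
      df[[cv]][runif(n) < config$missingness] <- NA
    }
  }
  df
}

#' Simulate a full synthetic cohort bundle
#'
#' Generates covariates, a correlated log-normal metabolite matrix with
#' planted age structure, the disease registry and trait tables, all
#' deterministically from `config$seed`. The returned bundle records the
#' configuration and every realized planted parameter as ground truth.
#'
#' @param config a [simulation_config()].
#' @return a `cohort_bundle` list with elements `participants`,
#'   `metabolites` (raw positive scale, participants x metabolites),
#'   `registry`, `traits`, `ground_truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "covariates"))
  participants <- gen_covariates(config)
  n <- config$n_participants; p <- config$n_metabolites

  set.seed(substream_seed(config$seed, "metabolites"))
  latent <- draw_latent(n, p, config$blocks)
  for (j in seq_len(p)) {
    mu <- planted_age_mean(config, j, participants$age)
    if (any(mu != 0)) latent[, j] <- latent[, j] + mu
  }
  dimnames(latent) <- list(participants$id, sprintf("met_%03d", seq_len(p)))

  bundle <- structure(list(participants = participants,
                           metabolites = exp(config$log_scale_sd * latent),
                           registry = NULL, traits = NULL,
                           ground_truth = list(config = config, realized = list())),
                      class = "cohort_bundle")
  bundle <- simulate_registry(bundle, config$diseases,
                              seed = substream_seed(config$seed, "registry"))
  bundle <- simulate_traits(bundle, config$traits,
                            seed = substream_seed(config$seed, "traits"))
  bundle
}

# z-scale the latent (log) metabolite matrix for linear predictors
latent_z <- function(bundle) {
  scale(log(bundle$metabolites))
}

#' Simulate the disease registry for an existing bundle
#'
#' Draws prevalent status from a logistic model on planted log-ORs,
#' incident onsets either from an exponential proportional-hazards model
#' (`hazard_driven`), or independently of the metabolome with a planted
#' pre-onset divergence added to cases' baseline metabolite values
#' (`divergence_driven`), or fully independently (`null`). Divergence is
#' applied on the latent (log) scale: the case's stored raw value becomes
#' `exp(log(value) + shift * ramp((E - t)/E))` where `t` is the
#' individual's eventual time to onset and `E` the planted emergence time.
#'
#' @param bundle a `cohort_bundle` with participants and metabolites.
#' @param disease_specs list of [disease_spec()].
#' @param seed integer seed.
#' @return the bundle with `registry` filled in (long format: one row per
#'   participant x non-never disease status) and divergence shifts applied
#'   to `metabolites`; realized parameters appended to the ground truth.
#' @export
simulate_registry <- function(bundle, disease_specs, seed) {
  set.seed(seed)
  n <- nrow(bundle$participants)
  horizon <- bundle$ground_truth$config$follow_up_horizon %||% 15
  ids <- vapply(disease_specs, function(d) d$disease_id, character(1))
  if (anyDuplicated(ids)) stop("disease_id collision: ", ids[duplicated(ids)][1L])
  rows <- list()
  z <- latent_z(bundle)
  for (spec in disease_specs) {
    lp <- rep(0, n)
    if (!is.null(spec$effect_metabolites)) {
      em <- spec$effect_metabolites
      lp <- as.vector(z[, em$metabolite, drop = FALSE] %*% em$effect)
    }
    prevalent <- if (spec$mode == "null") {
      runif(n) < spec$prevalence_prevalent
    } else {
      runif(n) < stats::plogis(qlogis(spec$prevalence_prevalent) + lp)
    }
    onset <- rep(NA_real_, n)
    if (spec$mode == "hazard_driven") {
      t_evt <- rexp(n, rate = pmax(spec$incidence_scale * exp(lp), 1e-300))
      incident <- !prevalent & t_evt <= horizon
      onset[incident] <- t_evt[incident]
    } else {
      p_case <- 1 - exp(-spec$incidence_scale * horizon)
      incident <- !prevalent & runif(n) < p_case
      onset[incident] <- runif(sum(incident), 0, horizon)
      if (spec$mode == "divergence_driven") {
        dv <- spec$divergence
        tto <- onset[incident]
        frac <- (dv$emergence_time - tto) / dv$emergence_time
        ramp <- if (dv$ramp == "step") as.numeric(tto <= dv$emergence_time)
                else pmin(pmax(frac, 0), 1)
        j <- dv$metabolite
        lsd <- bundle$ground_truth$config$log_scale_sd %||% 1
        bundle$metabolites[incident, j] <-
          bundle$metabolites[incident, j] * exp(lsd * dv$shift * ramp)
      }
    }
    status <- rep("never", n)
    status[incident] <- "incident"
    status[prevalent] <- "prevalent"
    keep <- status != "never"
    if (any(keep)) {
      rows[[spec$disease_id]] <- data.frame(
        id = bundle$participants$id[keep],
        disease_id = spec$disease_id,
        status = status[keep],
        onset_time = onset[keep],
        censor_time = horizon,
        stringsAsFactors = FALSE
      )
    }
    bundle$ground_truth$realized[[spec$disease_id]] <-
      list(spec = spec, n_prevalent = sum(prevalent), n_incident = sum(incident))
  }
  bundle$registry <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
                     else data.frame(id = character(), disease_id = character(),
                                     status = character(), onset_time = numeric(),
                                     censor_time = numeric())
  bundle$ground_truth$follow_up_horizon <- horizon
  bundle
}

#' Simulate trait tables for an existing bundle
#'
#' Continuous traits are linear in the z-scaled latent metabolites plus
#' Gaussian noise; binary traits are Bernoulli draws from a logistic
#' model; ordinal traits threshold a latent Gaussian into equal-probability
#' levels coded 1..L.
#'
#' @param bundle a `cohort_bundle`.
#' @param trait_specs list of [trait_spec()].
#' @param seed integer seed.
#' @return the bundle with `traits` filled (data.frame keyed by `id`).
#' @export
simulate_traits <- function(bundle, trait_specs, seed) {
  set.seed(seed)
  n <- nrow(bundle$participants)
  ids <- vapply(trait_specs, function(t) t$trait_id, character(1))
  if (anyDuplicated(ids)) stop("trait_id collision: ", ids[duplicated(ids)][1L])
  out <- data.frame(id = bundle$participants$id, stringsAsFactors = FALSE)
  z <- latent_z(bundle)
  for (spec in trait_specs) {
    lp <- rep(spec$intercept, n)
    if (!is.null(spec$effect_metabolites)) {
      em <- spec$effect_metabolites
      lp <- lp + as.vector(z[, em$metabolite, drop = FALSE] %*% em$effect)
    }
    val <- switch(spec$kind,
      continuous = lp + rnorm(n, 0, spec$noise_sd),
      binary = rbinom(n, 1L, stats::plogis(lp)),
      ordinal = {
        lat <- lp + rnorm(n, 0, spec$noise_sd)
        cuts <- quantile(lat, probs = seq_len(spec$n_ordinal_levels - 1L) /
                                 spec$n_ordinal_levels, type = 7)
        as.integer(cut(lat, c(-Inf, cuts, Inf), labels = FALSE))
      })
    out[[spec$trait_id]] <- val
    bundle$ground_truth$realized[[spec$trait_id]] <- list(spec = spec)
  }
  bundle$traits <- out
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>", nrow(x$participants), "participants x",
      ncol(x$metabolites), "metabolites;",
      length(unique(x$registry$disease_id)), "diseases;",
      max(0L, ncol(x$traits) - 1L), "traits\n")
  invisible(x)
}
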