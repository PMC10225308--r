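#' Default brain-behavior linkage matrix
#'
#' Standardized effect weights mapping the standardized predictors (age and
#' the four regional binding potentials) onto the agent parameters. The
#' default plants the headline association pattern: older age and lower
#' amygdala D2-like receptor availability increase stickiness (hence choice
#' inflexibility), and higher amygdala availability increases the optimism
#' bias of belief reports. All other entries are zero.
#'
#' @param regions Character vector of region names (columns after `age`).
#' @return A numeric matrix with rows `agent_param_names` and columns
#'   `c("age", regions)`.
#' @export
default_linkage <- function(regions = c("midbrain", "amygdala", "insula",
                                        "anterior_cingulate")) {
  W <- matrix(0, nrow = length(agent_param_names),
              ncol = length(regions) + 1L,
              dimnames = list(agent_param_names, c("age", regions)))
  if ("amygdala" %in% regions) {
    W["stickiness", "age"] <- 0.30
    W["stickiness", "amygdala"] <- -0.35
    W["belief_bias", "amygdala"] <- 0.30
  }
  W
}

default_regions <- function() {
  data.frame(
    region = c("midbrain", "amygdala", "insula", "anterior_cingulate"),
    mean = c(1.73, 3.08, 1.86, 1.19),
    sd = c(0.41, 0.80, 0.55, 0.38),
    age_slope = c(-0.45, -0.15, -0.40, -0.40),
    stringsAsFactors = FALSE
  )
}

#' Configure the synthetic cohort generator
#'
#' Describes the participant-level predictor set: ages on a fixed range and
#' regional dopamine D2-like non-displaceable binding potentials (BP_ND) with
#' target means/SDs, age slopes, and correlated region residuals, plus the
#' planted linkage from those predictors to the agent parameters.
#'
#' Region defaults match the four regions of interest where D2-like BP_ND is
#' typically quantified with [11C]FLB 457 (the striatum cannot be reliably
#' quantified with this ligand and is excluded): midbrain 1.73 (SD 0.41),
#' amygdala 3.08 (SD 0.80), insula 1.86 (SD 0.55), anterior cingulate 1.19
#' (SD 0.38). Default age slopes are negative, smallest in magnitude for the
#' amygdala, reflecting its relative preservation with age.
#'
#' @param n_participants Cohort size (>= 3).
#' @param age_range Length-2 numeric, inclusive age range in years.
#' @param regions Data frame with columns `region`, `mean`, `sd`, `age_slope`
#'   (standardized log-BP change per standardized age, |slope| < 1).
#' @param inter_region_corr Common correlation of region residuals on the
#'   standardized log scale.
#' @param linkage Weight matrix as in [default_linkage()]; rows
#'   `agent_param_names`, columns `c("age", regions$region)`.
#' @param param_base Named numeric vector of baseline agent parameters.
#' @param param_noise_sd Named numeric vector of residual SDs for each agent
#'   parameter.
#'
#' @return An object of class `cohort_config`.
#' @examples
#' cohort_config(n_participants = 50)
#' @export
cohort_config <- function(n_participants = 35,
                          age_range = c(26, 79),
                          regions = default_regions(),
                          inter_region_corr = 0.4,
                          linkage = default_linkage(regions$region),
                          param_base = c(stickiness = 1, risk_propensity = 0.85,
                                         inv_temperature = 1, belief_slope = 1,
                                         belief_bias = 0, report_noise = 15),
                          param_noise_sd = c(stickiness = 0.30,
                                             risk_propensity = 0.30,
                                             inv_temperature = 0.20,
                                             belief_slope = 0.15,
                                             belief_bias = 0.30,
                                             report_noise = 4)) {
  cfg <- list(n_participants = as.integer(n_participants),
              age_range = as.numeric(age_range),
              regions = regions,
              inter_region_corr = as.numeric(inter_region_corr),
              linkage = linkage,
              param_base = param_base,
              param_noise_sd = param_noise_sd)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid cohort configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (is.na(cfg$n_participants) || cfg$n_participants < 3L)
    stop_cfg("n_participants", "must be at least 3")
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) <= 0)
    stop_cfg("age_range", "must be c(min, max) with max > min")
  req <- c("region", "mean", "sd", "age_slope")
  if (!all(req %in% names(cfg$regions)))
    stop_cfg("regions", paste("must have columns", paste(req, collapse = ", ")))
  if (any(cfg$regions$sd <= 0) || any(cfg$regions$mean <= 0))
    stop_cfg("regions", "must have positive means and SDs")
  if (any(abs(cfg$regions$age_slope) >= 1))
    stop_cfg("regions", "must have |age_slope| < 1")
  if (abs(cfg$inter_region_corr) >= 1)
    stop_cfg("inter_region_corr", "must satisfy |corr| < 1")
  R <- region_residual_corr(cfg)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10)
    stop_cfg("inter_region_corr",
             "implies a residual covariance that is not positive definite")
  vars <- c("age", cfg$regions$region)
  if (!is.matrix(cfg$linkage) ||
      !identical(rownames(cfg$linkage), agent_param_names) ||
      !identical(colnames(cfg$linkage), vars))
    stop_cfg("linkage",
             sprintf("must be a matrix with rows {%s} and columns {%s}",
                     paste(agent_param_names, collapse = ", "),
                     paste(vars, collapse = ", ")))
  if (!all(agent_param_names %in% names(cfg$param_base)))
    stop_cfg("param_base", "must name every agent parameter")
  if (!all(agent_param_names %in% names(cfg$param_noise_sd)) ||
      any(cfg$param_noise_sd < 0))
    stop_cfg("param_noise_sd", "must name every agent parameter, all >= 0")
  invisible(cfg)
}

region_residual_corr <- function(cfg) {
  k <- nrow(cfg$regions)
  R <- matrix(cfg$inter_region_corr, k, k)
  diag(R) <- 1
  R
}

#' Sample a synthetic cohort of participants
#'
#' Ages are uniform on `age_range`. Binding potentials are generated on the
#' log scale: each region's standardized log-BP is `age_slope` times the
#' (population-)standardized age plus a correlated Gaussian residual scaled so
#' its variance is 1, then mapped through lognormal moment matching so the
#' population mean and SD of the natural-scale BP_ND equal the configured
#' targets. The log-scale construction guarantees BP_ND > 0 for every draw.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed.
#'
#' @return A data frame with `id`, `age`, and one BP_ND column per region.
#' @examples
#' head(sample_cohort(cohort_config(), seed = 1))
#' @export
sample_cohort <- function(cfg, seed = 1L) {
  validate_cohort_config(cfg)
  set.seed(as.integer(seed))
  n <- cfg$n_participants
  k <- nrow(cfg$regions)
  age <- stats::runif(n, cfg$age_range[1L], cfg$age_range[2L])
  # population standardization of the uniform age
  z_age <- (age - mean(cfg$age_range)) / (diff(cfg$age_range) / sqrt(12))

  R <- region_residual_corr(cfg)
  e <- matrix(stats::rnorm(n * k), n, k) %*% chol(R)
  slope <- cfg$regions$age_slope
  z <- sweep(e, 2L, sqrt(1 - slope^2), `*`) + outer(z_age, slope)

  # lognormal moment matching: E = mean, SD = sd on the natural scale
  m <- cfg$regions$mean
  s <- cfg$regions$sd
  sig2 <- log(1 + s^2 / m^2)
  mu <- log(m) - sig2 / 2
  bp <- exp(sweep(sweep(z, 2L, sqrt(sig2), `*`), 2L, mu, `+`))
  colnames(bp) <- cfg$regions$region
  data.frame(id = seq_len(n), age = age, bp, stringsAsFactors = FALSE)
}

#' Attach linked agent parameters to a sampled cohort
#'
#' Each agent parameter is `base + W z + noise`, where `z` is the
#' within-cohort standardized `(age, regions)` matrix, `W` the configured
#' linkage, and the noise Gaussian with the configured SD. Draws violating
#' the agent-parameter constraints (e.g. negative stickiness or
#' non-positive inverse temperature) are clamped to the nearest valid value.
#'
#' @param cohort Data frame from [sample_cohort()].
#' @param cfg The [cohort_config()] used to sample it.
#' @param seed Integer seed.
#'
#' @return `cohort` with the six agent-parameter columns appended.
#' @export
link_agent_params <- function(cohort, cfg, seed = 1L) {
  validate_cohort_config(cfg)
  vars <- c("age", cfg$regions$region)
  if (!all(vars %in% names(cohort)))
    stop("'cohort' lacks predictor columns: ",
         paste(setdiff(vars, names(cohort)), collapse = ", "), call. = FALSE)
  W <- cfg$linkage
  if (!identical(dim(W), c(length(agent_param_names), length(vars))))
    stop("linkage matrix W has wrong dimensions", call. = FALSE)
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  z <- scale(as.matrix(cohort[, vars]))
  base <- matrix(cfg$param_base[agent_param_names], n,
                 length(agent_param_names), byrow = TRUE)
  noise <- matrix(stats::rnorm(n * length(agent_param_names)), n,
                  length(agent_param_names))
  noise <- sweep(noise, 2L, cfg$param_noise_sd[agent_param_names], `*`)
  par <- base + z %*% t(W) + noise
  colnames(par) <- agent_param_names
  # clamp to the valid parameter space
  eps <- 1e-3
  par[, "stickiness"] <- pmax(par[, "stickiness"], 0)
  par[, "inv_temperature"] <- pmax(par[, "inv_temperature"], eps)
  par[, "belief_slope"] <- pmax(par[, "belief_slope"], eps)
  par[, "report_noise"] <- pmax(par[, "report_noise"], 0)
  cbind(cohort, as.data.frame(par))
}
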