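#' Default trait moments per taxonomic group
#'
#' Mean and standard deviation of body length (um), swimming speed (um/s)
#' and body aspect ratio for each group, as compiled across published
#' motility surveys, plus typical appendage geometry used when generating
#' synthetic cohorts. Sizes and speeds are strongly right-skewed across all
#' groups, hence the log-normal generator.
#'
#' @return A named list of per-group parameter lists.
#' @export
group_trait_defaults <- function() {
  list(
    bacteria = list(size = c(5.79, 9.33), speed = c(48.33, 98.47),
                    aspect = c(0.33, 0.20),
                    L = c(8.28, 4.0), lam = c(2.3, 0.7), h = c(0.3, 0.15),
                    f = c(100, 50)),
    spirochaete = list(size = c(18.59, 13.02), speed = c(17.94, 18.84),
                       aspect = c(0.02, 0.01)),
    spiroplasma = list(size = c(5.72, 0.28), speed = c(1.69, 0.81),
                       aspect = c(0.03, 0.005)),
    archaea = list(size = c(2.71, 2.12), speed = c(89.18, 126.57),
                   aspect = c(0.11, 0.06),
                   L = c(4.3, 1.5), lam = c(1.5, 0.5), h = c(0.2, 0.08),
                   f = c(25, 10)),
    flagellate = list(size = c(38.87, 56.64), speed = c(186.70, 208.77),
                      aspect = c(0.60, 0.27),
                      L = c(40, 25), lam = c(24, 10), h = c(4, 2),
                      f = c(35, 15)),
    spermatozoon = list(size = c(12.21, 17.25), speed = c(127.23, 78.49),
                        aspect = c(0.47, 0.30),
                        L = c(54, 20), lam = c(35, 8), h = c(8, 3),
                        f = c(20, 6)),
    ciliate = list(size = c(194.87, 207.45), speed = c(1147.57, 1375.64),
                   aspect = c(0.49, 0.22),
                   kappa = c(0.5, 0.3), ell = c(12, 5), f = c(25, 8)))
}

#' Configuration for a synthetic organism cohort
#'
#' @param group Taxonomic group, see [organism_groups()].
#' @param n Cohort size (>= 1).
#' @param size_mean,size_sd Body length moments in um.
#' @param speed_mean,speed_sd Swimming speed moments in um/s.
#' @param aspect_mean,aspect_sd Aspect ratio (W/B) moments; the generator
#'   truncates to (0, 1].
#' @param missingness Named list of per-field missingness rates in `[0, 1]`
#'   (e.g. `list(W = 0.3)` blanks the width of ~30% of records).
#' @param seed Integer seed; every random stream is derived from it.
#' @return An object of class `"cohort_config"`. Unspecified moments default
#'   to the group's values from [group_trait_defaults()].
#' @export
cohort_config <- function(group, n,
                          size_mean = NULL, size_sd = NULL,
                          speed_mean = NULL, speed_sd = NULL,
                          aspect_mean = NULL, aspect_sd = NULL,
                          missingness = list(), seed = 1L) {
  group <- match.arg(group, organism_groups())
  stopifnot(n >= 1)
  def <- group_trait_defaults()[[group]]
  size <- c(size_mean %||% def$size[1], size_sd %||% def$size[2])
  speed <- c(speed_mean %||% def$speed[1], speed_sd %||% def$speed[2])
  aspect <- c(aspect_mean %||% def$aspect[1], aspect_sd %||% def$aspect[2])
  if (any(c(size[1], speed[1], aspect[1]) <= 0))
    stop("cohort_config: means must be > 0", call. = FALSE)
  if (length(missingness) &&
      (any(unlist(missingness) < 0) || any(unlist(missingness) > 1)))
    stop("cohort_config: missingness rates must lie in [0, 1]",
         call. = FALSE)
  structure(list(group = group, n = as.integer(n), size = size,
                 speed = speed, aspect = aspect,
                 appendages = def[setdiff(names(def),
                                          c("size", "speed", "aspect"))],
                 missingness = missingness, seed = as.integer(seed)),
            class = "cohort_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log-normal parameters matching a target mean and sd
lognormal_params <- function(mean, sd) {
  sigma2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

# deterministic sub-seed per (seed, stream-name); stays below 2^31
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (abs(seed) * 7919L + h * 104729L) %% 2147483647L
}

draw_lognormal <- function(n, mean, sd, seed, name) {
  p <- lognormal_params(mean, sd)
  set.seed(substream_seed(seed, name))
  stats::rlnorm(n, p$mu, p$sigma)
}

draw_aspect <- function(n, mean, sd, seed, name = "aspect") {
  # truncated normal on (0, 1] via inverse-cdf; reject configs whose
  # untruncated mass on the support is negligible
  plo <- stats::pnorm(0, mean, sd)
  phi <- stats::pnorm(1, mean, sd)
  if (phi - plo < 0.05)
    stop("draw_aspect: moments put almost no mass in (0, 1]", call. = FALSE)
  set.seed(substream_seed(seed, name))
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic organism cohort
#'
#' Draws `n` organism records with right-skewed (log-normal) body lengths
#' and swimming speeds matching the configured means and standard
#' deviations, truncated-normal aspect ratios in (0, 1], and group-typical
#' appendage geometry (helix or wave parameters for flagellated groups,
#' ciliary density for ciliates). Fully deterministic given the seed: each
#' trait has its own derived random stream, so adding or removing a trait
#' does not reshuffle the others.
#'
#' @param config A [cohort_config()].
#' @return A list of [organism_record()]s.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config("ciliate", 10, seed = 42))
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  seed <- config$seed
  B <- draw_lognormal(n, config$size[1], config$size[2], seed, "B")
  U <- draw_lognormal(n, config$speed[1], config$speed[2], seed, "U")
  aspect <- draw_aspect(n, config$aspect[1], config$aspect[2], seed)
  W <- aspect * B
  app <- lapply(names(config$appendages), function(fld) {
    m <- config$appendages[[fld]]
    draw_lognormal(n, m[1], m[2], seed, fld)
  })
  names(app) <- names(config$appendages)

  blank <- function(fld) {
    rate <- config$missingness[[fld]]
    if (is.null(rate)) return(rep(FALSE, n))
    set.seed(substream_seed(seed, paste0("miss_", fld)))
    stats::runif(n) < rate
  }
  fields <- c(list(W = W, U = U), app)
  drop <- lapply(names(fields), blank)
  names(drop) <- names(fields)

  lapply(seq_len(n), function(i) {
    args <- list(species = sprintf("synthetic %s %03d", config$group, i),
                 group = config$group, B = B[i],
                 notes = "synthetic record")
    for (fld in names(fields))
      if (!drop[[fld]][i]) args[[fld]] <- fields[[fld]][i]
    do.call(organism_record, args)
  })
}

#' Forward-model observed speeds with known ground truth
#'
#' Fills the swimming speed `U` of each record with the prediction of a
#' chosen propulsion model at a known parameter value, optionally corrupted
#' by multiplicative log-normal noise of unit mean and given coefficient of
#' variation. Used for parameter-recovery tests of the inverse estimators:
#' at zero noise the corresponding `estimate_*` function must return the
#' ground truth exactly.
#'
#' @param records List of [organism_record()]s carrying the geometry the
#'   model needs.
#' @param model One of `"rft_torque"` (parameter `par` = motor torque in
#'   pN nm), `"stress"` (tau, mPa), `"force"` (force per cilium, pN),
#'   `"surface"` (surface speed, um/s).
#' @param par Ground-truth parameter; scalar or one value per record.
#' @param fluid A [fluid_medium()].
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (0 = noiseless).
#' @param seed Integer seed for the noise stream.
#' @param policy A [collapse_policy()].
#' @return The records with `U` filled; ground truth per record in the
#'   `"truth"` attribute (NA for records skipped for missing geometry,
#'   listed in the `"skipped"` attribute).
#' @export
forward_observe <- function(records,
                            model = c("rft_torque", "stress", "force",
                                      "surface"),
                            par, fluid = fluid_medium(), noise_cv = 0,
                            seed = 1L, policy = collapse_policy()) {
  model <- match.arg(model)
  n <- length(records)
  par <- rep_len(par, n)
  stopifnot(noise_cv >= 0)
  noise <- if (noise_cv > 0) {
    p <- lognormal_params(1, noise_cv)
    set.seed(substream_seed(seed, paste0("noise_", model)))
    stats::rlnorm(n, p$mu, p$sigma)
  } else rep(1, n)

  truth <- rep(NA_real_, n)
  skipped <- character(0)
  out <- records
  for (i in seq_len(n)) {
    rec <- records[[i]]
    U <- tryCatch({
      B <- field_value(rec, "B", policy)
      W <- field_value(rec, "W", policy)
      if (anyNA(c(B, W))) stop("missing body geometry")
      body <- spheroid_body(B, W)
      switch(model,
        rft_torque = {
          L <- field_value(rec, "L", policy)
          h <- field_value(rec, "h", policy)
          if (anyNA(c(L, h))) stop("missing flagellum geometry")
          lam <- field_value(rec, "lam", policy)
          if (is.na(lam)) lam <- 4 * pi * h
          xi_sq <- morphological_factor(body,
                                        helical_flagellum(L, lam, h))
          par[i] / (fluid$eta * xi_sq)
        },
        stress = speed_constant_stress(par[i], body, fluid),
        force = {
          arr <- ciliary_array(
            N = if (is.null(rec$N)) NULL else field_value(rec, "N", policy),
            kappa = if (is.null(rec$kappa)) NULL
                    else field_value(rec, "kappa", policy),
            d = if (is.null(rec$d)) NULL else field_value(rec, "d", policy))
          cnt <- cilia_count(arr, surface_area(body))
          if (is.null(cnt)) stop("missing cilia count")
          speed_constant_force(par[i], cnt$N, body, fluid)
        },
        surface = speed_surface_velocity(par[i], body$e))
    }, error = function(e) NA_real_)
    if (is.na(U)) {
      skipped <- c(skipped, rec$species)
      next
    }
    truth[i] <- par[i]
    rec$U <- quantity(point = U * noise[i])
    out[[i]] <- rec
  }
  attr(out, "truth") <- truth
  attr(out, "model") <- model
  attr(out, "skipped") <- skipped
  out
}
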