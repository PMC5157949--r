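# Piecewise demographic models.
#
# A model is an ordered set of epochs running from the present backwards in
# time. Time is measured in generations before present and epoch boundaries
# are half-open [start, end). Each epoch has a duration (the terminal epoch
# is unbounded), a diploid effective size at its most recent boundary, and a
# growth rate. A positive growth rate means the population was growing
# towards the present, i.e. the size shrinks as we move back in time:
# N(u) = size_recent * (1 + g)^(-u) within the epoch (compound-per-generation
# convention, the default) or N(u) = size_recent * exp(-g u) (exact
# exponential, growth_mode = "exponential"). Both reduce to
# N(u) = size_recent * exp(-rho u) with rho = log(1 + g) or rho = g.

#' Construct an epoch of a piecewise demographic model
#'
#' @param duration Epoch length in generations; `Inf` for the terminal epoch.
#' @param size Diploid effective population size at the epoch's most recent
#'   boundary.
#' @param growth_rate Per-generation growth rate towards the present
#'   (0 = constant size).
#' @return A one-row tibble.
#' @export
epoch <- function(duration, size, growth_rate = 0) {
  stopifnot(duration > 0, size > 0, is.finite(size))
  tibble::tibble(duration = as.numeric(duration), size = as.numeric(size),
                 growth_rate = as.numeric(growth_rate))
}

#' Construct a piecewise demographic model
#'
#' @param epochs A tibble of epochs (rows ordered from the present backwards),
#'   e.g. built by binding [epoch()] rows. Exactly the last epoch must be
#'   unbounded (`duration = Inf`) and constant in size.
#' @param name Model name used in output metadata.
#' @param growth_mode `"compound"` interprets `growth_rate` g as
#'   `(1+g)` fold change per generation; `"exponential"` as the instantaneous
#'   exponential rate.
#' @return An object of class `demog_model`.
#' @examples
#' demographic_model(epoch(Inf, 1e4), name = "constant-10k")
#' @export
demographic_model <- function(epochs, name = "model",
                              growth_mode = c("compound", "exponential")) {
  growth_mode <- match.arg(growth_mode)
  epochs <- dplyr::bind_rows(epochs)
  stopifnot(nrow(epochs) >= 1, all(epochs$size > 0), all(epochs$duration > 0))
  k <- nrow(epochs)
  if (!is.infinite(epochs$duration[k]) || any(is.infinite(epochs$duration[-k]))) {
    stop("exactly the last epoch must have infinite duration")
  }
  if (epochs$growth_rate[k] != 0) stop("the terminal epoch must be constant")
  rho <- if (growth_mode == "compound") log1p(epochs$growth_rate) else epochs$growth_rate
  epochs$rho <- rho
  epochs$t_start <- cumsum(c(0, epochs$duration[-k]))
  structure(list(epochs = epochs, name = name, growth_mode = growth_mode),
            class = "demog_model")
}

#' @export
print.demog_model <- function(x, ...) {
  cat(sprintf("<demographic model '%s'> %d epochs (%s growth)\n",
              x$name, nrow(x$epochs), x$growth_mode))
  print(x$epochs[c("duration", "size", "growth_rate")])
  invisible(x)
}

#' @export
tidy.demog_model <- function(x, ...) {
  dplyr::mutate(x$epochs, name = x$name)
}

#' Diploid population size at a time in the past
#'
#' @param model A `demog_model`.
#' @param t Vector of times in generations before present.
#' @return Diploid sizes `N(t)`.
#' @export
population_size <- function(model, t) {
  stopifnot(inherits(model, "demog_model"), all(t >= 0))
  ep <- model$epochs
  idx <- findInterval(t, ep$t_start)
  ep$size[idx] * exp(-ep$rho[idx] * (t - ep$t_start[idx]))
}

# Cumulative pairwise coalescent intensity Lambda(t) = int_0^t du / (2 N(u)).
pair_intensity <- function(model, t) {
  ep <- model$epochs
  vapply(t, function(tt) {
    acc <- 0
    for (e in seq_len(nrow(ep))) {
      a <- ep$t_start[e]
      if (tt <= a) break
      b <- min(tt, a + ep$duration[e])
      acc <- acc + segment_intensity(ep$size[e], ep$rho[e], b - a)
      if (b == tt) break
    }
    acc
  }, numeric(1))
}

# intensity accumulated over the first s generations of an epoch
segment_intensity <- function(N_recent, rho, s) {
  if (s <= 0) return(0)
  if (rho == 0) s / (2 * N_recent) else expm1(rho * s) / (2 * N_recent * rho)
}

# inverse of segment_intensity in s (may return Inf if the epoch cannot
# accumulate `target` intensity -- impossible for rho >= 0 epochs of finite N)
segment_intensity_inverse <- function(N_recent, rho, target) {
  if (rho == 0) 2 * N_recent * target else log1p(2 * N_recent * rho * target) / rho
}

# time t at which pair intensity reaches `target` (target >= 0)
pair_intensity_inverse <- function(model, target) {
  ep <- model$epochs
  acc <- 0
  for (e in seq_len(nrow(ep))) {
    seg <- segment_intensity(ep$size[e], ep$rho[e], ep$duration[e])
    if (acc + seg >= target || e == nrow(ep)) {
      return(ep$t_start[e] + segment_intensity_inverse(ep$size[e], ep$rho[e], target - acc))
    }
    acc <- acc + seg
  }
  stop("unreachable")
}

# matrix handed to the C++ simulator: duration, size, rho per epoch
epoch_matrix <- function(model) {
  as.matrix(model$epochs[c("duration", "size", "rho")])
}

# total duration of the non-terminal epochs (start of the terminal epoch)
terminal_start <- function(model) {
  ep <- model$epochs
  ep$t_start[nrow(ep)]
}

# ---------------------------------------------------------------------------
# Presets

#' Constant-size demographic model
#'
#' @param size Diploid effective population size.
#' @return A `demog_model`.
#' @export
demog_constant <- function(size = 10000) {
  demographic_model(epoch(Inf, size), name = sprintf("constant-%g", size))
}

#' European demographic model of Tennessen et al. (2012)
#'
#' Single-population (European lineage) parameterization of the model of
#' Tennessen et al. (2012, Nature 486:216), built on Gravel et al. (2011):
#' ancestral size 7,310 diploids; expansion to 14,474 at 5,920 generations
#' before present; out-of-Africa bottleneck to 1,861 at 2,040 generations;
#' European founding size 1,032 at 920 generations followed by exponential
#' growth at 0.307% per generation; accelerated growth at 1.95% per
#' generation over the last 204.6 generations. Growth rates are instantaneous
#' exponential rates as published; migration between the African and
#' European demes of the original two-population model is ignored.
#'
#' @return A `demog_model`.
#' @export
demog_tennessen_eur <- function() {
  t_growth2 <- 5115 / 25   # 204.6 generations
  t_eu <- 23000 / 25       # 920 generations
  t_ooa <- 51000 / 25      # 2040 generations
  t_af <- 148000 / 25      # 5920 generations
  n_eu0 <- 1032
  r1 <- 0.00307
  r2 <- 0.0195
  n_mid <- n_eu0 * exp(r1 * (t_eu - t_growth2))
  n_now <- n_mid * exp(r2 * t_growth2)
  demographic_model(
    dplyr::bind_rows(
      epoch(t_growth2, n_now, r2),
      epoch(t_eu - t_growth2, n_mid, r1),
      epoch(t_ooa - t_eu, 1861),
      epoch(t_af - t_ooa, 14474),
      epoch(Inf, 7310)
    ),
    name = "tennessen-eur", growth_mode = "exponential"
  )
}

#' European demographic model of Nelson et al. (2012)
#'
#' Two-epoch parameterization transcribed from Nelson et al. (2012, Science
#' 337:100): a constant ancestral size of 7,700 diploids followed by
#' exponential growth over the last 375 generations to a present effective
#' size of about 4 million diploids (instantaneous growth rate
#' `log(4e6 / 7700) / 375` per generation, about 1.67%).
#'
#' @param size_now Present diploid effective size.
#' @param onset Growth onset, generations before present.
#' @param size_ancestral Ancestral diploid size.
#' @return A `demog_model`.
#' @export
demog_nelson_eur <- function(size_now = 4e6, onset = 375, size_ancestral = 7700) {
  r <- log(size_now / size_ancestral) / onset
  demographic_model(
    dplyr::bind_rows(
      epoch(onset, size_now, r),
      epoch(Inf, size_ancestral)
    ),
    name = "nelson-eur", growth_mode = "exponential"
  )
}

#' Modified Nelson model with a re-estimated recent growth epoch
#'
#' The most recent epoch uses a present effective population size of
#' 4,009,877 diploids with exponential growth onset 119.47 generations in the
#' past at 5.38% per generation (compound-per-generation convention).
#' Older epochs default to the constant ancestral size of the Nelson et al.
#' (2012) model (7,700 diploids); supply `ancient` to override them.
#'
#' @param ancient Optional tibble of older epochs (ordered past-wards,
#'   terminal epoch last) replacing the default constant ancestral epoch.
#' @return A `demog_model`.
#' @export
demog_modified_nelson <- function(ancient = NULL) {
  if (is.null(ancient)) ancient <- epoch(Inf, 7700)
  demographic_model(
    dplyr::bind_rows(epoch(119.47, 4009877, 0.0538), ancient),
    name = "modified-nelson", growth_mode = "compound"
  )
}

#' Named demographic presets
#'
#' @param name One of `"constant"`, `"tennessen"`, `"nelson"`,
#'   `"modified_nelson"`.
#' @return A `demog_model`.
#' @export
demog_preset <- function(name) {
  switch(name,
    constant = demog_constant(),
    tennessen = demog_tennessen_eur(),
    nelson = demog_nelson_eur(),
    modified_nelson = demog_modified_nelson(),
    stop("unknown demographic preset: ", name)
  )
}

# ---------------------------------------------------------------------------
# YAML serialization

#' Write a demographic model to YAML
#'
#' @param model A `demog_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_demog_yaml <- function(model, path) {
  stopifnot(inherits(model, "demog_model"))
  eps <- purrr::pmap(model$epochs[c("duration", "size", "growth_rate")],
                     function(duration, size, growth_rate) {
                       list(duration_generations = if (is.infinite(duration)) "inf" else duration,
                            diploid_size = size, growth_rate = growth_rate)
                     })
  yaml::write_yaml(list(name = model$name, growth_mode = model$growth_mode,
                        epochs = eps), path)
  invisible(path)
}

#' Read a demographic model from YAML
#'
#' @param path YAML file written by [write_demog_yaml()] or hand-authored in
#'   the same schema.
#' @return A `demog_model`.
#' @export
read_demog_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  eps <- dplyr::bind_rows(purrr::map(y$epochs, function(e) {
    d <- e$duration_generations
    if (identical(d, "inf")) d <- Inf
    epoch(d, e$diploid_size, e$growth_rate %||% 0)
  }))
  demographic_model(eps, name = y$name %||% "model",
                    growth_mode = y$growth_mode %||% "compound")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
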