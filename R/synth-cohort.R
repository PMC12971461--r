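#' Specification for a synthetic per-animal cohort
#'
#' Generates a small (predictor, response) table with a known linear
#' relationship, emulating the per-animal histology-versus-seizure-metric
#' regressions: response = slope * predictor + intercept + N(0, noise_sd),
#' with predictors equally spaced over `predictor_range`.
#'
#' @param n_animals number of animals (>= 3).
#' @param slope,intercept true regression line.
#' @param noise_sd Gaussian noise SD on the response (>= 0).
#' @param predictor_range numeric length-2 interval for the predictor.
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_animals = 6, slope = 1, intercept = 0,
                        noise_sd = 0.2, predictor_range = c(0, 1),
                        seed = 1L) {
  if (n_animals < 3) stop("n_animals must be at least 3")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (diff(predictor_range) <= 0)
    stop("predictor_range must be an increasing interval")
  structure(list(n_animals = as.integer(n_animals), slope = slope,
                 intercept = intercept, noise_sd = noise_sd,
                 predictor_range = predictor_range,
                 seed = as.integer(seed)), class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `animal`, `predictor`, `response`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  x <- seq(spec$predictor_range[1], spec$predictor_range[2],
           length.out = spec$n_animals)
  y <- withr::with_seed(spec$seed,
    spec$slope * x + spec$intercept +
      stats::rnorm(spec$n_animals, 0, spec$noise_sd))
  data.frame(animal = seq_len(spec$n_animals), predictor = x,
             response = y)
}
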