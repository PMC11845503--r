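#' Symptom-linked distortion variants D0-D6
#'
#' The model space crosses three candidate mechanisms by which a mental
#' health score can distort global SPE formation: a confidence-learning
#' distortion (slope \code{beta_c} on the confidence asymmetry), a
#' feedback-learning distortion (slope \code{beta_f} on the feedback
#' asymmetry), and a report bias (slope \code{beta_a} added to the reported
#' SPE). The seven variants are:
#' \describe{
#'   \item{D0}{no distortion (all slopes fixed at 0)}
#'   \item{D1}{confidence distortion only (\code{beta_c} free)}
#'   \item{D2}{feedback distortion only (\code{beta_f} free)}
#'   \item{D3}{response bias only (\code{beta_a} free)}
#'   \item{D4}{confidence + feedback distortions}
#'   \item{D5}{confidence distortion + response bias}
#'   \item{D6}{feedback distortion + response bias}
#' }
#'
#' @param variant One of \code{"D0"} ... \code{"D6"}.
#' @return A \code{distortion_spec}: the variant label and a named logical
#'   vector \code{free} over \code{beta_c}, \code{beta_f}, \code{beta_a}.
#' @export
distortion_spec <- function(variant = "D0") {
  variant <- match.arg(variant, paste0("D", 0:6))
  free <- switch(variant,
    D0 = c(beta_c = FALSE, beta_f = FALSE, beta_a = FALSE),
    D1 = c(beta_c = TRUE,  beta_f = FALSE, beta_a = FALSE),
    D2 = c(beta_c = FALSE, beta_f = TRUE,  beta_a = FALSE),
    D3 = c(beta_c = FALSE, beta_f = FALSE, beta_a = TRUE),
    D4 = c(beta_c = TRUE,  beta_f = TRUE,  beta_a = FALSE),
    D5 = c(beta_c = TRUE,  beta_f = FALSE, beta_a = TRUE),
    D6 = c(beta_c = FALSE, beta_f = TRUE,  beta_a = TRUE))
  structure(list(variant = variant, free = free), class = "distortion_spec")
}

#' @export
print.distortion_spec <- function(x, ...) {
  frees <- names(x$free)[x$free]
  cat(sprintf("<distortion_spec> %s (free slopes: %s)\n", x$variant,
              if (length(frees)) paste(frees, collapse = ", ") else "none"))
  invisible(x)
}

#' Group-level model parameters
#'
#' Container for the free parameters of the belief model. \code{mu0} and
#' \code{v0} are per-task (perception, memory) initial-belief mean and
#' variance; \code{dlr_f0} and \code{dlr_c0} are learning-rate asymmetry
#' intercepts (optionally split by task via \code{sharing}); \code{beta_f},
#' \code{beta_c}, \code{beta_a} are regression slopes of the symptom score
#' on the feedback asymmetry, confidence asymmetry, and reported SPE.
#'
#' @param mu0 Named numeric (perception, memory) in (0, 1), or a scalar
#'   recycled to both tasks.
#' @param v0 Named numeric like \code{mu0}; each must satisfy
#'   \code{v0 < mu0 * (1 - mu0)}.
#' @param dlr_f0,dlr_c0 Asymmetry intercepts in (-1, 1); length 1 if shared
#'   across tasks, length 2 (named) if split.
#' @param beta_f,beta_c,beta_a Symptom-regression slopes (per raw symptom
#'   unit).
#' @param sharing Either \code{"shared"} (one intercept per asymmetry
#'   family) or \code{"per_task"}.
#' @return A \code{model_params} object.
#' @export
model_params <- function(mu0 = c(perception = 0.7, memory = 0.7),
                         v0 = c(perception = 0.015, memory = 0.015),
                         dlr_f0 = 0, dlr_c0 = 0,
                         beta_f = 0, beta_c = 0, beta_a = 0,
                         sharing = c("shared", "per_task")) {
  sharing <- match.arg(sharing)
  mu0 <- expand_task(mu0, "mu0")
  v0 <- expand_task(v0, "v0")
  if (any(mu0 <= 0 | mu0 >= 1)) stop("'mu0' must lie in (0, 1)")
  if (any(v0 <= 0 | v0 >= mu0 * (1 - mu0)))
    stop("'v0' must lie in (0, mu0*(1-mu0)) for each task")
  dlr_f0 <- expand_dlr(dlr_f0, sharing, "dlr_f0")
  dlr_c0 <- expand_dlr(dlr_c0, sharing, "dlr_c0")
  if (any(abs(c(dlr_f0, dlr_c0)) >= 1))
    stop("asymmetry intercepts must lie strictly inside (-1, 1)")
  structure(list(mu0 = mu0, v0 = v0, dlr_f0 = dlr_f0, dlr_c0 = dlr_c0,
                 beta_f = beta_f, beta_c = beta_c, beta_a = beta_a,
                 sharing = sharing),
            class = "model_params")
}

expand_task <- function(x, what) {
  tasks <- c("perception", "memory")
  if (length(x) == 1 && is.null(names(x))) x <- stats::setNames(rep(x, 2), tasks)
  if (!all(tasks %in% names(x))) stop("'", what, "' needs perception and memory entries")
  x[tasks]
}

expand_dlr <- function(x, sharing, what) {
  if (sharing == "shared") {
    if (length(x) != 1) stop("'", what, "' must be scalar when sharing = 'shared'")
    return(unname(x))
  }
  expand_task(x, what)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  mu0: P=%.3f M=%.3f   v0: P=%.4f M=%.4f\n",
              x$mu0[1], x$mu0[2], x$v0[1], x$v0[2]))
  cat(sprintf("  dlr_f0: %s   dlr_c0: %s   (%s)\n",
              paste(signif(x$dlr_f0, 3), collapse = "/"),
              paste(signif(x$dlr_c0, 3), collapse = "/"), x$sharing))
  cat(sprintf("  beta_f=%.4g beta_c=%.4g beta_a=%.4g\n",
              x$beta_f, x$beta_c, x$beta_a))
  invisible(x)
}

#' Effective learning-rate asymmetries for one participant
#'
#' Symptom scores enter the model through linear regressions on the
#' asymmetry parameters:
#' \deqn{\Delta LR_f = \Delta LR_{f0} + \beta_f \cdot MH_i, \quad
#'       \Delta LR_c = \Delta LR_{c0} + \beta_c \cdot MH_i,}
#' with each slope forced to zero unless the active distortion variant
#' frees it. Effective values are hard-clipped to (-0.99, 0.99) so that
#' every belief increment stays positive.
#'
#' @param params A \code{model_params}.
#' @param spec A \code{distortion_spec}.
#' @param mh Symptom score (raw questionnaire units).
#' @param task \code{"perception"} or \code{"memory"}; only relevant when
#'   intercepts are split per task.
#' @return Named numeric \code{c(dlr_f = , dlr_c = )}.
#' @export
effective_asymmetries <- function(params, spec, mh, task = "perception") {
  f0 <- if (params$sharing == "shared") params$dlr_f0 else params$dlr_f0[[task]]
  c0 <- if (params$sharing == "shared") params$dlr_c0 else params$dlr_c0[[task]]
  bf <- if (spec$free["beta_f"]) params$beta_f else 0
  bc <- if (spec$free["beta_c"]) params$beta_c else 0
  c(dlr_f = clip01(f0 + bf * mh, -0.99, 0.99),
    dlr_c = clip01(c0 + bc * mh, -0.99, 0.99))
}

#' Enumerate the base-model asymmetry structures
#'
#' Before any symptom terms enter, five versions of the belief model are
#' compared that differ in how the asymmetry parameters are shared: none
#' (all zero), one shared asymmetry, split by update type (feedback vs
#' confidence), split by task, or fully split.
#'
#' @return A data.frame with columns \code{label}, \code{by_type} (are
#'   feedback and confidence asymmetries distinct?), \code{by_task}, and
#'   \code{n_dlr} (number of free asymmetry parameters).
#' @export
base_model_variants <- function() {
  data.frame(
    label = c("zero", "shared", "split_type", "split_task", "split_both"),
    by_type = c(NA, FALSE, TRUE, FALSE, TRUE),
    by_task = c(NA, FALSE, FALSE, TRUE, TRUE),
    n_dlr = c(0L, 1L, 2L, 2L, 4L),
    stringsAsFactors = FALSE)
}
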