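#' Soft-bound STDP weight change for a single spike pair
#'
#' Weight change for one pre/post spike pair with timing difference
#' \eqn{\Delta T = t_{post} - t_{pre}}:
#' potentiation \eqn{+A_+(1 - g/g_{max})e^{-\Delta T/\gamma_+}} for
#' \eqn{\Delta T > 0}, depression
#' \eqn{-A_-(g/g_0)e^{\Delta T/\gamma_-}} for \eqn{\Delta T < 0}, and zero for
#' coincident spikes. The weight-dependent factors vanish at the bounds,
#' keeping the rule in the soft-bound regime.
#'
#' @param g Current weight (vectorised with `delta_T`).
#' @param delta_T Spike-time difference, ms.
#' @param params An [stdp_params()].
#' @return Weight change (not clipped; see [clip_weight()]).
#' @export
#' @examples
#' stdp_delta(0, 10, stdp_params(g_0 = 0.1))  # 0.02 * exp(-1)
stdp_delta <- function(g, delta_T, params) {
  stopifnot(inherits(params, "stdp_params"))
  ifelse(delta_T > 0,
         params$A_plus * (1 - g / params$g_max) * exp(-delta_T / params$gamma_plus),
         ifelse(delta_T < 0,
                -params$A_minus * (g / params$g_0) * exp(delta_T / params$gamma_minus),
                0))
}

#' Clip a synaptic weight to its hard bounds
#'
#' @param g Weight (vectorised).
#' @param params An [stdp_params()] supplying `g_min` and `g_max`.
#' @return `min(max(g, g_min), g_max)`.
#' @export
clip_weight <- function(g, params) {
  stopifnot(inherits(params, "stdp_params"))
  pmin(pmax(g, params$g_min), params$g_max)
}

#' Event-driven online STDP for one plastic synapse
#'
#' All-to-all pairing implemented with per-neuron exponential traces: on a
#' postsynaptic spike the synapse potentiates by
#' \eqn{A_+(1 - g/g_{max})\,x_{pre}} where the presynaptic trace
#' \eqn{x_{pre}} sums \eqn{e^{-\Delta t/\gamma_+}} over all earlier pre
#' spikes; on a presynaptic spike it depresses by
#' \eqn{A_-(g/g_0)\,x_{post}} analogously. Updates are applied sequentially
#' in spike-time order and (by default) clipped after each event; coincident
#' pre/post spikes contribute nothing. This trace formulation is exactly the
#' pairwise sum of [stdp_delta()] over all spike pairs when weight dependence
#' is frozen, and is the same scheme the compiled network engine applies.
#'
#' @param pre_times,post_times Spike times of the pre- and postsynaptic
#'   neuron, ms.
#' @param g0 Initial weight.
#' @param params An [stdp_params()].
#' @param clip Clip after every event (default `TRUE`).
#' @return List with `g` (final weight), `path` (data frame `time`, `g` after
#'   each event) and `n_events`.
#' @export
stdp_weight_path <- function(pre_times, post_times, g0, params, clip = TRUE) {
  stopifnot(inherits(params, "stdp_params"))
  ev_t <- c(pre_times, post_times)
  ev_pre <- c(rep(TRUE, length(pre_times)), rep(FALSE, length(post_times)))
  ord <- order(ev_t, !ev_pre)  # at ties: depression (pre event) first
  ev_t <- ev_t[ord]; ev_pre <- ev_pre[ord]
  g <- g0
  x_pre <- 0; x_post <- 0; t_last <- -Inf
  out_t <- numeric(length(ev_t)); out_g <- numeric(length(ev_t))
  i <- 1
  while (i <= length(ev_t)) {
    t <- ev_t[i]
    if (is.finite(t_last)) {
      x_pre <- x_pre * exp(-(t - t_last) / params$gamma_plus)
      x_post <- x_post * exp(-(t - t_last) / params$gamma_minus)
    }
    t_last <- t
    j <- i
    while (j <= length(ev_t) && ev_t[j] == t) j <- j + 1
    here <- i:(j - 1)
    # pass 1: updates against traces that exclude this instant's spikes
    for (k in here) {
      if (ev_pre[k]) {
        g <- g - params$A_minus * (g / params$g_0) * x_post
      } else {
        g <- g + params$A_plus * (1 - g / params$g_max) * x_pre
      }
      if (clip) g <- clip_weight(g, params)
      out_t[k] <- t; out_g[k] <- g
    }
    # pass 2: trace increments
    x_pre <- x_pre + sum(ev_pre[here])
    x_post <- x_post + sum(!ev_pre[here])
    i <- j
  }
  list(g = g, path = data.frame(time = out_t, g = out_g),
       n_events = length(ev_t))
}

#' Predicted mean weight change from a spike-timing-difference distribution
#'
#' Integrates the (weight-independent) STDP window against the measured
#' distribution \eqn{f(\Delta T)}:
#' \deqn{\bar{\Delta g} = -\int_{-\infty}^{0} A_- e^{\Delta T/\gamma_-}
#'   f(\Delta T)\,d\Delta T + \int_0^{\infty} A_+ e^{-\Delta T/\gamma_+}
#'   f(\Delta T)\,d\Delta T}
#' The sign of the result predicts the direction of synaptic modification
#' (potentiation vs depression), independent of the simulated weight path; it
#' is used as an independent cross-check of simulated weight changes.
#'
#' With the default `g = NULL` the learning rates enter unweighted (the bare
#' integral above). Because the potentiation and depression rates are
#' asymmetric (`A_plus = 2 A_minus`), that bare form is positive even for a
#' flat distribution; supplying an evaluation weight `g` applies the
#' soft-bound factors \eqn{(1 - g/g_{max})} and \eqn{(g/g_0)} to the two
#' branches, and at the baseline weight (`g = g_0` with the study parameters)
#' the two rates balance exactly, so a flat distribution predicts zero change
#' and the sign tracks the asymmetry of \eqn{f(\Delta T)} alone. Use the
#' baseline-evaluated form when comparing against simulated weight changes.
#'
#' @param hist A [delta_t_histogram()] (normalised density over ms bins).
#' @param params An [stdp_params()].
#' @param g Optional weight at which to evaluate the soft-bound factors
#'   (e.g. `params$g_0`); `NULL` for the bare form.
#' @return Mean weight change per pairing event (scalar).
#' @export
predicted_mean_change <- function(hist, params, g = NULL) {
  stopifnot(inherits(hist, "delta_t_histogram"), inherits(params, "stdp_params"))
  mids <- (head(hist$edges, -1) + tail(hist$edges, -1)) / 2
  widths <- diff(hist$edges)
  a_pot <- params$A_plus
  a_dep <- params$A_minus
  if (!is.null(g)) {
    a_pot <- a_pot * (1 - g / params$g_max)
    a_dep <- a_dep * (g / params$g_0)
  }
  w <- ifelse(mids > 0, a_pot * exp(-mids / params$gamma_plus),
              ifelse(mids < 0, -a_dep * exp(mids / params$gamma_minus), 0))
  sum(w * hist$density * widths)
}

#' Soft-bound STDP fixed point under unstructured firing
#'
#' With a flat spike-timing-difference distribution the potentiation and
#' depression rates balance where
#' \eqn{A_+(1 - g^\ast/g_{max})\gamma_+ = A_-(g^\ast/g_0)\gamma_-}, giving
#' \deqn{g^\ast = \frac{A_+\gamma_+}{A_+\gamma_+/g_{max} + A_-\gamma_-/g_0}.}
#' With the default parameters (\eqn{A_+ = 2A_-}, \eqn{\gamma_+ = \gamma_-},
#' \eqn{g_{max} = 2g_0}) this equals \eqn{g_0}: baseline weights are a stable
#' operating point of the rule in the asynchronous regime.
#'
#' @param params An [stdp_params()].
#' @return The fixed-point weight \eqn{g^\ast}.
#' @export
stdp_fixed_point <- function(params) {
  stopifnot(inherits(params, "stdp_params"))
  num <- params$A_plus * params$gamma_plus
  num / (num / params$g_max + params$A_minus * params$gamma_minus / params$g_0)
}
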