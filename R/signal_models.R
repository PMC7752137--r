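#' Monoexponential spin-echo signal models
#'
#' Signal equations for saturation-recovery T1 weighting and spin-echo T2
#' decay: `t1_signal()` evaluates \eqn{S = M_0 (1 - e^{-TR/T_1})} and
#' `t2_signal()` evaluates \eqn{S = M_0 e^{-TE/T_2}}.  These are the forward
#' models fitted voxelwise by [relax_fit()] and [fit_map()], and the models
#' the synthetic phantom generator images through.
#'
#' @param m0 Equilibrium signal amplitude (arbitrary signal units).
#' @param t1,t2 Relaxation time constant in ms; must be `> 0`.
#' @param tr,te Repetition / echo time in ms; must be `>= 0`.
#' @return Signal in the units of `m0`.  All arguments recycle like ordinary
#'   arithmetic, so whole parameter maps can be imaged in one call.
#' @examples
#' t1_signal(8000, 150, 150)   # 8000 * (1 - exp(-1))
#' t2_signal(8000, 75, 36.6)
#' @export
t1_signal <- function(m0, t1, tr) {
  if (any(!is.finite(t1)) || any(t1 <= 0))
    zf_domain_error("t1 must be finite and > 0")
  if (any(tr < 0)) zf_domain_error("tr must be >= 0")
  m0 * (1 - exp(-tr / t1))
}

#' @rdname t1_signal
#' @export
t2_signal <- function(m0, t2, te) {
  if (any(!is.finite(t2)) || any(t2 <= 0))
    zf_domain_error("t2 must be finite and > 0")
  if (any(te < 0)) zf_domain_error("te must be >= 0")
  m0 * exp(-te / t2)
}

relax_signal <- function(model, m0, t_value, times) {
  if (model == "T1") t1_signal(m0, t_value, times)
  else t2_signal(m0, t_value, times)
}
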