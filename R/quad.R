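# Adaptive quadrature wrapper. stats::integrate with tight tolerances and a
# hard failure on non-convergence, so quadrature problems surface as errors
# with a diagnostic instead of silently wrong moments.
quad <- function(f, lower, upper, rel.tol = 1e-11, abs.tol = 1e-13,
                 subdivisions = 2000L) {
  res <- tryCatch(
    stats::integrate(f, lower, upper, rel.tol = rel.tol, abs.tol = abs.tol,
                     subdivisions = subdivisions, stop.on.error = FALSE),
    error = function(e) stop("quadrature failed on [", format(lower), ", ",
                             format(upper), "]: ", conditionMessage(e)))
  if (!res$message %in% c("OK", "roundoff error was detected"))
    stop("quadrature did not converge on [", format(lower), ", ",
         format(upper), "]: ", res$message)
  res$value
}
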