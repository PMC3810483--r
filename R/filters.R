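#' Dual-tree filter banks
#'
#' Analysis filter pairs for the two trees of the dual-tree complex wavelet
#' transform.  The first decomposition level uses the Farras nearly symmetric
#' orthonormal pair; deeper levels use the orthonormal 10-tap q-shift pair,
#' whose half-sample delay difference makes the two trees' wavelets an
#' approximate Hilbert pair.  Synthesis filters are the time-reversed analysis
#' filters (orthonormal perfect-reconstruction banks).
#'
#' @return A list with elements `first` and `qshift`, each a list of two
#'   trees; every tree is a list with `lo` and `hi` numeric filter vectors.
#' @keywords internal
dt_filter_bank <- function() {
  # Farras nearly symmetric filters for the first stage
  fa1 <- c(0, -0.08838834764832, 0.08838834764832, 0.69587998903400,
           0.69587998903400, 0.08838834764832, -0.08838834764832,
           0.01122679215254, 0.01122679215254, 0)
  fa1h <- c(0, -0.01122679215254, 0.01122679215254, 0.08838834764832,
            0.08838834764832, -0.69587998903400, 0.69587998903400,
            -0.08838834764832, -0.08838834764832, 0)
  fa2 <- c(0.01122679215254, 0.01122679215254, -0.08838834764832,
           0.08838834764832, 0.69587998903400, 0.69587998903400,
           0.08838834764832, -0.08838834764832, 0, 0)
  fa2h <- c(0, 0, -0.08838834764832, -0.08838834764832, 0.69587998903400,
            -0.69587998903400, 0.08838834764832, 0.08838834764832,
            0.01122679215254, -0.01122679215254)
  # Kingsbury orthonormal 10-tap q-shift filters for levels >= 2
  qa1 <- c(0.03516384000000, 0, -0.08832942000000, 0.23389032000000,
           0.76027237000000, 0.58751830000000, 0, -0.11430184000000, 0, 0)
  qa1h <- c(0, 0, -0.11430184000000, 0, 0.58751830000000,
            -0.76027237000000, 0.23389032000000, 0.08832942000000, 0,
            -0.03516384000000)
  qa2 <- rev(qa1)
  qa2h <- c(-0.03516384000000, 0, 0.08832942000000, 0.23389032000000,
            -0.76027237000000, 0.58751830000000, 0, -0.11430184000000, 0, 0)
  list(
    first = list(
      list(lo = fa1, hi = fa1h),
      list(lo = fa2, hi = fa2h)
    ),
    qshift = list(
      list(lo = qa1, hi = qa1h),
      list(lo = qa2, hi = qa2h)
    )
  )
}
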