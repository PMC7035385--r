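# CODATA 2018 physical constants (SI), >= 10 significant digits where defined.
.h_planck <- 6.62607015e-34    # J s (exact)
.m_electron <- 9.1093837015e-31 # kg
.e_charge <- 1.602176634e-19   # C (exact)
.c_light <- 299792458          # m/s (exact)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
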