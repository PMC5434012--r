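# internal numeric helpers shared across modules

# linear predictors are clipped at +/- 700 before exponentiation so that
# exp() never overflows; this never binds at realistic estimates (tested)
.clip_lp <- function(x, bound = 700) pmin(pmax(x, -bound), bound)

.expit <- function(x) 1 / (1 + exp(-.clip_lp(x)))

# logistic distribution tail used by the log-logistic AFT submodel
.logis_surv <- function(w) 1 / (1 + exp(.clip_lp(w)))

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

.is_binary01 <- function(x) all(x %in% c(0L, 1L))
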