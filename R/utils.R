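# internal helpers shared across modules

# absolute tolerance for comparisons of statistic values; breakpoints closer
# than this are merged
.v_tol <- 1e-12

# run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# classed conditions so the CLI can map failures to exit codes
elrStop <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

usageStop <- function(msg) elrStop(msg, "elr_usage_error")
dataStop  <- function(msg) elrStop(msg, "elr_data_error")
guardStop <- function(msg) elrStop(msg, "elr_guard_error")

# filesystem-safe key for a (censoring vector, n1, epsilon) triple: the bits
# of c are packed into hex so the key is short and collision-free
distributionKey <- function(cens, n1, epsilon) {
  bits <- as.integer(cens)
  pad <- (-length(bits)) %% 8L
  raw <- packBits(as.raw(c(bits, integer(pad))), type = "raw")
  sprintf("n%d_m%d_e%s_%s", length(bits), as.integer(n1),
          format(epsilon, digits = 15), paste(format(raw), collapse = ""))
}

# Clopper-Pearson interval for b successes out of r trials
clopperPearson <- function(b, r, conf = 0.95) {
  ci <- stats::binom.test(b, r, conf.level = conf)$conf.int
  c(low = ci[1], high = ci[2])
}
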