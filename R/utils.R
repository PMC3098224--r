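# internal helpers shared across modules

# Run `code` under a fixed RNG seed, leaving the caller's RNG state untouched.
# seed = NULL means "use the current RNG stream" (irreproducible by design).
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# One master seed expands deterministically into per-stage child seeds so that
# multi-stage experiments are reproducible stage by stage.  Documented scheme:
# child = (master + 10007 * stage + 101 * rep) mod (2^31 - 1), stages numbered
# in pipeline order (generate = 1, theory = 2, ring = 3, simulate = 4, ...).
child_seed <- function(master, stage, rep = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  as.integer((as.double(master) + 10007 * stage + 101 * rep) %% 2147483647)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(
      sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper),
      class = "hawkesnet_parameter_error"
    )
  }
  invisible(x)
}

check_prob <- function(x, name) check_scalar(x, name, 0, 1)

# YAML 1.1 resolves bare keys y/n/yes/no to booleans; our configs use `n`
# for the node count, so restore boolean-mangled names after read_yaml().
read_config_yaml <- function(path) {
  fix <- function(x) {
    if (!is.list(x)) return(x)
    nm <- names(x)
    if (!is.null(nm)) {
      nm[nm == "FALSE"] <- "n"
      nm[nm == "TRUE"] <- "y"
      names(x) <- nm
    }
    lapply(x, fix)
  }
  fix(yaml::read_yaml(path))
}

# Geodesic distance on a ring of n nodes between 0-based positions a and b.
ring_distance <- function(a, b, n) {
  d <- abs(a - b) %% n
  pmin(d, n - d)
}
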