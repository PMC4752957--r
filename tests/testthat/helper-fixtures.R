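# Fixture builders shared across test files. Deliberately simple and
# independent of simulate_factorial() where a test uses them as an oracle.

# balanced gaussian factorial built by direct arithmetic
make_gaussian_factorial <- function(nd, ns, r, vd, vs, vds, vr, seed) {
  set.seed(seed)
  dam <- factor(rep(sprintf("D%02d", seq_len(nd)), each = ns * r))
  sire <- factor(rep(rep(sprintf("S%02d", seq_len(ns)), each = r), nd))
  fam_idx <- rep(seq_len(nd * ns), each = r)
  y <- rnorm(nd, 0, sqrt(vd))[as.integer(dam)] +
    rnorm(ns, 0, sqrt(vs))[as.integer(sire)] +
    rnorm(nd * ns, 0, sqrt(vds))[fam_idx] +
    rnorm(nd * ns * r, 0, sqrt(vr))
  data.frame(dam = dam, sire = sire, y = y)
}

# random replicate-level count table (two outcome columns)
make_count_table <- function(n_fam = 12, seed = 1) {
  set.seed(seed)
  data.frame(
    dam = rep(sprintf("D%d", 1:4), each = n_fam / 4),
    sire = rep(sprintf("S%d", 1:3), n_fam / 3),
    replicate = "R1",
    alive = rpois(n_fam, 6),
    dead = rpois(n_fam, 3)
  )
}

# component matrix with the minimum columns the interval code needs
fake_component_matrix <- function(values, total = NULL, d = NULL, N = NULL) {
  out <- data.frame(iteration = seq_along(values), dam = values,
                    total = total %||% values, check.names = FALSE)
  class(out) <- c("component_matrix", class(out))
  if (!is.null(d)) attr(out, "d") <- d
  if (!is.null(N)) attr(out, "N") <- N
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
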