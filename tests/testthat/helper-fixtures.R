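# shared fixtures, built once per test run

tmpl_R <- make_template_foot("R")
tmpl_L <- make_template_foot("L")

.row1 <- function(x) if (is.matrix(x)) x[1L, , drop = FALSE] else matrix(x, 1L)

# random rotation matrix from a seeded draw (uniform axis, uniform angle)
random_rotation <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# apply a rigid transform (R, t) to every marker of a named list
transform_markers <- function(markers, R, tr = c(0, 0, 0)) {
  lapply(markers, function(p) {
    pm <- if (is.matrix(p)) p else matrix(p, 1L)
    out <- pm %*% t(R) + matrix(tr, nrow(pm), 3L, byrow = TRUE)
    if (is.matrix(p)) out else drop(out)
  })
}

# marker set whose joint geometry is generic (no coincidental symmetry),
# derived from the template by a small seeded jitter that keeps anatomy valid
jittered_markers <- function(sd = 2) {
  lapply(tmpl_R$markers, function(p) p + stats::rnorm(3, 0, sd))
}
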