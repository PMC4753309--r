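# Shared fixtures and independent oracles used across the suite.

osp <- siteConfig("osp")
beowulf <- siteConfig("beowulf")

# independent oracle for exponential parameters: log-linear regression
loglinear_oracle <- function(t, x) {
  co <- coef(lm(log(x) ~ t))
  c(x0 = unname(exp(co[1])), k = unname(co[2]))
}

# element-wise Bray-Curtis oracle, kept independent of the implementation
bray_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)

# pooled-variance two-sample t oracle (textbook form)
student_t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tt, df = df, p = 2 * pt(abs(tt), df, lower.tail = FALSE))
}

# a small deterministic community matrix with named taxa/samples
toy_counts <- function() {
  matrix(c(100, 50, 10,
           80, 60, 40),
         nrow = 3,
         dimnames = list(c("taxA", "taxB", "taxC"), c("s1", "s2")))
}
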