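# independent oracles: aov() error strata for the F decomposition, and
# car::Anova for Mauchly's test and the Greenhouse-Geisser epsilon

aov_oracle <- function(y) {
  n <- nrow(y)
  long <- data.frame(
    y = as.vector(y),
    subject = factor(rep(seq_len(n), 6)),
    cap = factor(rep(rep(c("gel", "dry"), each = 3), each = n)),
    phase = factor(rep(rep(c("II", "IV", "V"), 2), each = n))
  )
  s <- summary(stats::aov(y ~ cap * phase + Error(subject / (cap * phase)),
                          data = long))
  get_f <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, c("F value", "Pr(>F)")]
  }
  list(cap = get_f("Error: subject:cap", "cap"),
       phase = get_f("Error: subject:phase", "phase"),
       inter = get_f("Error: subject:cap:phase", "cap:phase"))
}

car_oracle <- function(y) {
  idata <- data.frame(cap = factor(rep(c("gel", "dry"), each = 3)),
                      phase = factor(rep(c("II", "IV", "V"), 2)))
  mod <- stats::lm(y ~ 1)
  s <- summary(car::Anova(mod, idata = idata, idesign = ~ cap * phase,
                          type = 3), multivariate = FALSE)
  list(sph = s$sphericity.tests, adj = s$pval.adjustments)
}

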