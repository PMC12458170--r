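# shared fixtures and independent oracles

study_scheme <- build_hardi_scheme(1)
study_model <- compartment_model()
study_design <- rsi_design(study_scheme, study_model)

# full 31-coefficient vector of an rsi_coefficients object
full_coef <- function(co) c(co$restricted, co$hindered, co$free)

# a physically plausible random coefficient vector (positive isotropic
# parts so the b0 validity gate passes)
random_mixture_coef <- function(seed) {
  withr::with_seed(seed, {
    x <- rnorm(31, 0, 0.05)
    x[c(1, 16, 31)] <- runif(3, 0.3, 0.8)
    x
  })
}

# isotropic three-compartment signal straight from the kernel spherical
# means (exactly inside the model span)
isotropic_signal <- function(fr, fh, ff, scheme = study_scheme,
                             model = study_model) {
  r0 <- vapply(scheme$bvals, compartment_response, numeric(1),
               model = model, compartment = "restricted", l = 0)
  h0 <- vapply(scheme$bvals, compartment_response, numeric(1),
               model = model, compartment = "hindered", l = 0)
  fr * r0 + fh * h0 + ff * exp(-scheme$bvals * model$free_diffusivity)
}

# brute-force Benjamini-Hochberg step-up, independent of p.adjust
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  # enforce step-up monotonicity from the largest rank down
  if (m > 1) {
    for (i in rev(seq_len(m - 1))) {
      adj[i] <- min(adj[i], adj[i + 1])
    }
  }
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
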