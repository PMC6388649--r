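# fixtures built in code

# a small fully-complete cohort spec
smallSpec <- function(nFASD = 12, nControl = 14, effect = 0.8,
                      seed = 42, nSnippets = 4L, rateHz = 40) {
  cohortSpec(nFASD = nFASD, nControl = nControl,
             effectSizes = c(prosac = effect, antisac = effect,
                             mgsac = effect, dti = effect, psych = effect,
                             naturalview = effect),
             missingness = NULL,
             traceSpec = list(nSnippets = nSnippets, rateHz = rateHz,
                              effectSnippets = seq_len(min(2L, nSnippets))),
             seed = seed)
}

# linearly separable toy: one perfect feature among pure noise
separableToy <- function(n = 40, nNoise = 5, seed = 1) {
  set.seed(seed)
  y <- rep(c("control", "FASD"), each = n / 2)
  x <- cbind(sep = ifelse(y == "FASD", 1, 0) + rnorm(n, 0, 0.05),
             matrix(rnorm(n * nNoise), n, nNoise,
                    dimnames = list(NULL, paste0("noise", seq_len(nNoise)))))
  list(x = x, y = y)
}

# snippet representations with group signal in the first few snippets
signalReps <- function(n = 30, nSnippets = 12, dims = 8,
                       signalSnippets = 4, shift = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c("control", "FASD"), each = n / 2)
  reps <- lapply(seq_len(nSnippets), function(s) {
    m <- matrix(rnorm(n * dims), n, dims)
    if (s <= signalSnippets)
      m[y == "FASD", seq_len(min(3, dims))] <-
        m[y == "FASD", seq_len(min(3, dims))] + shift
    m
  })
  list(reps = reps, y = y)
}

# per-assessment probability columns driven by independent latent signals
syntheticProbTable <- function(n = 46, nFASD = 22, strength = 1,
                               cols = c("a", "b"), seed = 1) {
  set.seed(seed)
  y <- rep(c("FASD", "control"), c(nFASD, n - nFASD))
  z <- ifelse(y == "FASD", strength, -strength)
  p <- vapply(cols, function(cc) plogis(z + rnorm(n)), numeric(n))
  colnames(p) <- cols
  list(probs = p, y = y)
}
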