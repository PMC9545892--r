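# Shared fixtures, built once per test run and memoised. All synthetic;
# nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

# Small stimulus set (6 images/category at 128 px), 64-filter bank and the
# shape/texture model RSMs over the 8 category x filter conditions.
demo_fixture <- function() {
  if (is.null(.fixtures$demo))
    .fixtures$demo <- demo_model_rsms(n_per_category = 6L, size_px = 128L)
  .fixtures$demo
}

bank128 <- function() demo_fixture()$bank

# Construct a neural RSM object directly (for regression-level tests that
# need full control over the outcome matrix).
make_neural <- function(m, labels, subject_id = "s01") {
  dimnames(m) <- list(labels, labels)
  structure(list(subject_id = subject_id, labels = labels, matrix = m,
                 fisher_z_applied = FALSE),
            class = "neural_rsm")
}

# Construct a model RSM object directly.
make_rsm <- function(m, labels, variant = NULL) {
  dimnames(m) <- list(labels, labels)
  structure(list(labels = labels, matrix = m, variant = variant),
            class = "rsm")
}

# Per-scan model RSMs from the demo fixture.
scan_model_rsms <- function(filter_type = "frequency") {
  d <- demo_fixture()
  labs <- scan_conditions(filter_type)
  list(shape = subset_rsm(d$shape, labs),
       texture = subset_rsm(d$texture, labs))
}
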