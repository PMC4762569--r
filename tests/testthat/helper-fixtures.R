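# Shared fixture builders and numeric comparison helpers.

# element-wise relative error with a safe scale for exact zeros
max_rel_err <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  sc <- pmax(abs(a), abs(b))
  sc[sc == 0] <- 1
  max(abs(a - b) / sc)
}

expect_sigdigits <- function(a, b, digits = 6) {
  expect_lt(max_rel_err(a, b), 10^(-digits) * 5)
}

tiny_curve <- function(metadata = c(sample_description = "lysozyme")) {
  saxs_curve(c(0.01, 0.02, 0.03), c(100, 99, 97), err = c(1, 1.1, 1.2),
             metadata = metadata)
}

# a small random CIF model for round-trip property tests
random_cif <- function(seed) {
  set.seed(seed)
  rnd_name <- function() {
    paste0(sample(letters, sample(2:6, 1), replace = TRUE), collapse = "")
  }
  rnd_value <- function() {
    pool <- c("plain", "two words", "it's", "?", ".", "3.14", "-1e-5",
              "line1\nline2", "", "data_x", "loop_", "#notcomment",
              "\"dq\"", "a'b")
    sample(pool, 1)
  }
  f <- cif_new()
  for (b in seq_len(sample(1:3, 1))) {
    lab <- paste0("BLK", b)
    for (ct in seq_len(sample(1:3, 1))) {
      n_items <- sample(1:4, 1)
      loop <- runif(1) < 0.5
      n_rows <- if (loop) sample(1:5, 1) else 1L
      items <- setNames(
        lapply(seq_len(n_items), function(i) {
          vapply(seq_len(n_rows), function(j) rnd_value(), character(1))
        }),
        vapply(seq_len(n_items), function(i) paste0("it", i, rnd_name()),
               character(1)))
      f <- cif_set_category(f, lab, paste0("cat_", ct, "_", rnd_name()),
                            items, loop = loop)
    }
  }
  f
}
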