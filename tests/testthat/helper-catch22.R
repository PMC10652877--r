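# Seeded reference series used to pin the 22 statistics against the
# independent numpy/scipy implementation (data-raw/catch22_oracle.py).
# Regenerated identically at test time; the frozen expected values live in
# catch22-reference.csv.
c22_ref_series <- function(i, n = 500) {
  with_seed(1000 + i, switch(i,
    rnorm(n),                                                  # white noise
    as.numeric(stats::filter(rnorm(n), 0.8, "recursive")),     # AR(1) +
    sin(2 * pi * 5 * seq_len(n) / n) + rnorm(n, 0, 0.3),       # slow sine
    0.01 * seq_len(n) + rnorm(n),                              # trend + noise
    runif(n),                                                  # uniform iid
    as.numeric(stats::filter(rnorm(n), -0.5, "recursive")),    # AR(1) -
    sin(2 * pi * 20 * seq_len(n) / n) + rnorm(n),              # fast sine
    cumsum(rnorm(n)),                                          # random walk
    stats::rt(n, df = 3),                                      # heavy tails
    as.numeric(stats::filter(rnorm(n), c(0.5, 0.3), "recursive"))  # AR(2)
  ))
}
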