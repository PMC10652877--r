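# Regenerates tests/testthat/catch22-reference.csv: expected values of the 22
# statistics on the 10 seeded reference series, computed by the independent
# numpy/scipy implementation in catch22_oracle.py. Run from the package root:
#   Rscript data-raw/freeze_catch22.R
pkgload::load_all(".", quiet = TRUE)
source("tests/testthat/helper-catch22.R")

series <- t(sapply(1:10, c22_ref_series))
tmp_in <- tempfile(fileext = ".csv")
tmp_out <- tempfile(fileext = ".csv")
write.table(series, tmp_in, sep = ",", row.names = FALSE, col.names = FALSE)
status <- system2("python", c("data-raw/catch22_oracle.py", tmp_in, tmp_out))
stopifnot(status == 0)
ref <- read.csv(tmp_out, header = FALSE)
colnames(ref) <- catch22_names()
write.csv(cbind(series_id = 1:10, signif(ref, 15)),
          "tests/testthat/catch22-reference.csv", row.names = FALSE)
cat("froze", nrow(ref), "series x", ncol(ref), "statistics\n")
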