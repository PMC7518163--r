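# Five full default-condition pipeline runs (the virtual-species recovery
# study), computed once and shared by every test that interrogates them.
.recoveryCache <- new.env(parent = emptyenv())

recoveryRuns <- function(seeds = 1:5) {
  key <- paste(seeds, collapse = "-")
  if (is.null(.recoveryCache[[key]]))
    .recoveryCache[[key]] <- lapply(seeds, function(s)
      runPipeline(sdmConfig(seed = s)))
  .recoveryCache[[key]]
}

truthSpearman <- function(run) {
  res <- run$results[[1]]
  tv <- envValues(res$truth)
  ev <- envValues(res$ensemble@meanMap)
  ok <- !is.na(tv) & !is.na(ev)
  cor(tv[ok], ev[ok], method = "spearman")
}
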