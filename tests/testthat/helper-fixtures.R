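## Shared fixtures: one synthetic plastome reused across test files
## (helpers are sourced once per test run).

shared_sim <- plastidpoly::simulate_genome(seed = 42L)

## a miniature annotated linear layout for hand-built GFF3 tests
write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
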