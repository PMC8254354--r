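# Shared fixtures, built once per test run and memoised (simulation takes a
# few seconds; many test files reuse the same stated-world defaults).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# default planted-truth world: 598 bp W region, 9 deletions / 230 bp,
# 20 F + 20 M at 12-15x Poisson depth
default_world <- function() {
  cached("world", function() {
    ref <- simulate_reference(seed = 101L)
    sheet <- default_cohort()
    tables <- simulate_depth(ref$layout, sheet, depth_model(), seed = 102L)
    list(ref = ref, sheet = sheet, tables = tables)
  })
}

# the default world's paralog alignment, boundary-trimmed
default_alignment <- function() {
  cached("alignment", function() {
    w <- default_world()
    iv <- w$ref$layout$w_locus
    rs <- substr(w$ref$genome[[iv$contig]], iv$start, iv$end)
    hit <- find_paralog(rs, w$ref$genome, self_exclude = iv)
    ss <- substr(w$ref$genome[[hit$contig]], hit$start, hit$end)
    tr <- trim_terminal_gaps(global_align(rs, ss, a_id = "w", b_id = "shared"))
    list(aln = tr$aln, hit = hit, region_seq = rs, subject_seq = ss)
  })
}

# one full pipeline run on a simulated fixture
default_run <- function() {
  cached("run", function() {
    out <- file.path(tempdir(), "sexscan-default-run")
    summary <- run_all(run_config(out, seed = 7L))
    list(summary = summary, dir = out)
  })
}
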