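test_that("run_serial executes, skips on rerun, and records status", {
  step <- make_cp_step(2L)
  res <- run_serial(step)
  expect_equal(res$state, c("done", "done"))
  expect_true(all(file.exists(vapply(step$outfiles, `[[`, "", 1))))
  expect_equal(res$exit_code, c(0L, 0L))
  # idempotence: immediate rerun launches nothing
  res2 <- run_serial(step)
  expect_equal(res2$state, c("skipped", "skipped"))
  expect_true(all(is.na(res2$exit_code)))
  # force reruns everything
  res3 <- run_serial(step, force = TRUE)
  expect_equal(res3$state, c("done", "done"))
  # registry returns the last result per sample, in timestamp order
  st <- status(file.path(step$outdir, ".logs"), "copy")
  expect_equal(nrow(st), 2L)
  expect_equal(st$state, c("done", "done"))
})

test_that("a failing sample is recorded failed and does not stop the run", {
  dir <- tempfile(); dir.create(dir)
  ins <- file.path(dir, c("a.txt", "missing.txt"))
  writeLines("x", ins[1])  # second input does not exist -> cp fails
  tgt <- targets_table(data.frame(FileName1 = ins,
                                  SampleName = c("S1", "S2")))
  pf <- tempfile()
  writeLines(c("software\t\tcp", "infile\t\t<FileName1>",
               "outfile\t\t<SampleName>.out"), pf)
  step <- build_sysargs(tgt, read_param(pf), "copy",
                        outdir = file.path(dir, "res"))
  res <- run_serial(step)
  expect_equal(res$state, c("done", "failed"))
  expect_true(res$exit_code[2] != 0L)
  expect_true(file.exists(res$log_path[2]))
  # restart completes exactly the remaining sample once its input appears
  writeLines("y", ins[2])
  res2 <- run_serial(step)
  expect_equal(res2$state, c("skipped", "done"))
})

test_that("unknown software is refused before any launch", {
  step <- make_cp_step(1L)
  step$software <- "no-such-binary-xyz"
  step$args[[1]][1] <- "no-such-binary-xyz"
  expect_error(run_serial(step), "not found on PATH")
  expect_false(file.exists(step$outfiles[[1]][1]))
})

test_that("failed partial outputs are renamed and never count as complete", {
  dir <- tempfile(); dir.create(dir)
  writeLines("x", file.path(dir, "in.txt"))
  tgt <- targets_table(data.frame(FileName1 = file.path(dir, "in.txt"),
                                  SampleName = "S1"))
  # 'false' exits nonzero; pre-create a partial output to simulate a crash
  pf <- tempfile()
  writeLines(c("software\t\tfalse", "infile\t\t<FileName1>",
               "outfile\t\t<SampleName>.out"), pf)
  step <- build_sysargs(tgt, read_param(pf), "bad",
                        outdir = file.path(dir, "res"))
  dir.create(step$outdir)
  writeLines("partial", step$outfiles[[1]][1])
  res <- run_serial(step, force = TRUE)
  expect_equal(res$state, "failed")
  expect_false(file.exists(step$outfiles[[1]][1]))
  expect_true(file.exists(paste0(step$outfiles[[1]][1], ".failed")))
  expect_equal(completed(step), FALSE)
})

test_that("run_parallel matches run_serial states and preserves row order", {
  step_s <- make_cp_step(8L)
  step_p <- make_cp_step(8L)
  rs <- run_serial(step_s)
  rp <- run_parallel(step_p, workers = 4L)
  expect_equal(rp$state, rs$state)
  expect_equal(rp$sample_name, paste0("S", 1:8))
  # workers = 1 degenerates to serial behaviour
  rp1 <- run_parallel(make_cp_step(3L), workers = 1L)
  expect_equal(rp1$state, rep("done", 3))
})

test_that("one failing sample among eight fails alone under parallelism", {
  dir <- tempfile(); dir.create(dir)
  ins <- file.path(dir, paste0("in", 1:8, ".txt"))
  for (f in ins[-5]) writeLines("x", f)  # input 5 missing
  tgt <- targets_table(data.frame(FileName1 = ins,
                                  SampleName = paste0("S", 1:8)))
  pf <- tempfile()
  writeLines(c("software\t\tcp", "infile\t\t<FileName1>",
               "outfile\t\t<SampleName>.out"), pf)
  step <- build_sysargs(tgt, read_param(pf), "copy",
                        outdir = file.path(dir, "res"))
  res <- run_parallel(step, workers = 4L)
  expect_equal(sum(res$state == "failed"), 1L)
  expect_equal(sum(res$state == "done"), 7L)
  expect_equal(res$state[5], "failed")
})

test_that("status survives corrupted registry lines and empty directories", {
  expect_equal(nrow(status(tempfile(), "nope")), 0L)
  step <- make_cp_step(2L)
  run_serial(step)
  reg <- file.path(step$outdir, ".logs", "copy", "status.jsonl")
  cat("NOT JSON AT ALL\n", file = reg, append = TRUE)
  expect_warning(st <- status(file.path(step$outdir, ".logs"), "copy"),
                 "corrupted")
  expect_equal(nrow(st), 2L)
  # forced rerun strictly advances per-sample timestamps
  Sys.sleep(0.02)
  run_serial(step, force = TRUE)
  st2 <- suppressWarnings(status(file.path(step$outdir, ".logs"), "copy"))
  expect_true(all(st2$finished >= st$finished))
})
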