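#!/usr/bin/env Rscript
# Thin command-line wrapper over the adipomr package.
#
#   adipomr run --config <yaml> [--out <dir>]
#   adipomr report <run_dir>
#
# Exit codes: 0 ok, 2 configuration error, 3 stage failure.

suppressPackageStartupMessages(library(adipomr))

args <- commandArgs(trailingOnly = TRUE)
usage <- function() {
  cat("usage: adipomr run --config <yaml> [--out <dir>]\n",
      "       adipomr report <run_dir>\n", sep = "")
  quit(status = 2)
}
if (!length(args)) usage()

cmd <- args[1]
rest <- args[-1]
get_opt <- function(flag) {
  i <- match(flag, rest)
  if (is.na(i) || i == length(rest)) NULL else rest[i + 1]
}

if (cmd == "run") {
  cfg <- get_opt("--config")
  if (is.null(cfg)) usage()
  if (!file.exists(cfg)) {
    message("config file not found: ", cfg)
    quit(status = 2)
  }
  out <- get_opt("--out")
  status <- tryCatch({
    s <- run_pipeline(cfg, out_dir = out)
    cat("run complete:", s$out_dir, "\n")
    0L
  }, error = function(e) {
    message("pipeline failed: ", conditionMessage(e))
    3L
  })
  quit(status = status)
} else if (cmd == "report") {
  if (!length(rest)) usage()
  status <- tryCatch({
    cat(make_report(rest[1]), "\n")
    0L
  }, error = function(e) {
    message("report failed: ", conditionMessage(e))
    3L
  })
  quit(status = status)
} else {
  usage()
}
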