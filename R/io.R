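# Tabular interchange: headered, tab-separated, UTF-8, '.' decimal.
# Nested results go to JSON; run configuration round-trips through YAML.

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write per-sample count tables of a cohort
#'
#' One TSV per sample (pos, ref, A_fwd .. T_rev) plus `truth.tsv`,
#' `ages.tsv`, `samples.tsv` and the configuration as `config.yaml`.
#'
#' @param cohort a `het_cohort`.
#' @param dir output directory (created).
#' @return dir, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in unique(cohort$counts$sample)) {
    tab <- cohort$counts[cohort$counts$sample == s,
                         c("pos", "ref", COUNT_COLS)]
    write_tsv(tab, file.path(dir, paste0(s, ".counts.tsv")))
  }
  write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  write_tsv(cohort$ages, file.path(dir, "ages.tsv"))
  write_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  cfg <- cohort$config
  cfg$recurrent_sites <- as.list(cfg$recurrent_sites)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a directory of per-sample count tables
#'
#' Expects the layout of [write_cohort()]; sample identity is parsed
#' from file names `<individual>_<tissue>.counts.tsv`.
#'
#' @param dir input directory.
#' @return list with `counts` (long data.frame), `samples`, and `ages`
#'   when present.
#' @export
read_counts_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.counts\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("no *.counts.tsv files in ", dir)
  counts <- do.call(rbind, lapply(files, function(f) {
    s <- sub("\\.counts\\.tsv$", "", basename(f))
    parts <- strsplit(s, "_")[[1]]
    tab <- read_tsv(f)
    cbind(sample = s, individual = paste(utils::head(parts, -1), collapse = "_"),
          tissue = utils::tail(parts, 1), tab, stringsAsFactors = FALSE)
  }))
  out <- list(counts = counts)
  sm <- file.path(dir, "samples.tsv")
  if (file.exists(sm)) out$samples <- read_tsv(sm)
  ag <- file.path(dir, "ages.tsv")
  if (file.exists(ag)) out$ages <- read_tsv(ag)
  out
}

#' Write a result list as JSON
#' @param x list (must be JSON-representable).
#' @param path output file.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
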