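#' Write a generation log
#'
#' Tab-separated with a header row and a stable column order. Numeric
#' columns are written with 17 significant digits so a round trip through
#' [read_generation_log()] reproduces the values to machine precision. A
#' lockfile (`<path>.lock`) guards the file while it is being written;
#' attempting to write while another writer holds the lock is an error.
#'
#' @param records data.frame of records (may have zero rows: a header-only
#'   file is written).
#' @param path output path.
#' @param append append to an existing file (header suppressed).
#' @return `path`, invisibly.
#' @export
write_generation_log <- function(records, path, append = FALSE) {
  stopifnot(is.data.frame(records))
  lock <- paste0(path, ".lock")
  if (file.exists(lock))
    stop("log file is locked by another writer: ", path)
  file.create(lock)
  on.exit(unlink(lock), add = TRUE)
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !append, append = append, na = "NA")
  invisible(path)
}

#' @rdname write_generation_log
#' @export
read_generation_log <- function(path) {
  read.delim(path, sep = "\t", check.names = FALSE)
}

#' Save a simulation run to a directory
#'
#' Writes `manifest.yaml` (resolved configuration, seed, RNG and package
#' version), `generations.tsv` (per-colony summaries) and `population.tsv`
#' (parent genotype snapshots, one row per individual).
#'
#' @param sim a `"dol_sim"` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_run <- function(sim, dir) {
  stopifnot(inherits(sim, "dol_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_manifest(sim$config, dir)
  write_generation_log(sim$generations, file.path(dir, "generations.tsv"))
  al <- sim$alleles
  if (nrow(al)) {
    long <- rbind(
      data.frame(generation = al$generation, colony = al$colony,
                 role = "mother",
                 setNames(al[paste0("mother_", .loci)], .loci)),
      data.frame(generation = al$generation, colony = al$colony,
                 role = "father",
                 setNames(al[paste0("father_", .loci)], .loci)))
    long <- long[order(long$generation, long$colony, long$role), ]
  } else {
    long <- data.frame(generation = numeric(), colony = numeric(),
                       role = character())
  }
  write_generation_log(long, file.path(dir, "population.tsv"))
  invisible(dir)
}
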