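#' Read / write binned fragment counts
#'
#' Counts are exchanged as wide TSV: BED3 columns (`chrom`, `start`, `end`,
#' 0-based half-open) followed by one integer column per sample. Writing
#' then reading reproduces values and ordering exactly.
#'
#' @param path TSV file.
#' @param genome Optional `ffa_genome`; when given, the file's bin set must
#'   match the genome's exactly (first offending bin is reported).
#' @return Integer matrix (bins x samples) with sample columns; bin
#'   coordinates attached as attribute `bins`.
#' @export
read_bin_counts <- function(path, genome = NULL) {
  if (!file.exists(path)) stop(sprintf("counts file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(names(df)[1:3], c("chrom", "start", "end")))
    stop("counts TSV must start with columns chrom, start, end")
  bins <- df[, 1:3]
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  if (ncol(m) > 0) {
    if (any(m != floor(m))) stop("non-integer count in counts file")
    if (any(m < 0)) {
      bad <- which(m < 0, arr.ind = TRUE)[1, ]
      stop(sprintf("negative count at %s:%d (sample %s)",
                   bins$chrom[bad[1]], bins$start[bad[1]],
                   colnames(m)[bad[2]]))
    }
    storage.mode(m) <- "integer"
  }
  if (!is.null(genome)) {
    same <- nrow(bins) == genome$n_bins &&
      all(bins$chrom == genome$bins$chrom) &&
      all(bins$start == genome$bins$start) && all(bins$end == genome$bins$end)
    if (!same) {
      k <- min(nrow(bins), genome$n_bins)
      i <- which(bins$chrom[seq_len(k)] != genome$bins$chrom[seq_len(k)] |
                 bins$start[seq_len(k)] != genome$bins$start[seq_len(k)] |
                 bins$end[seq_len(k)] != genome$bins$end[seq_len(k)])
      i <- if (length(i)) i[1] else k + 1L
      stop(sprintf("bin set mismatch vs genome starting at file row %d (%s:%s)",
                   i, bins$chrom[min(i, nrow(bins))],
                   bins$start[min(i, nrow(bins))]))
    }
  }
  attr(m, "bins") <- bins
  m
}

#' @rdname read_bin_counts
#' @param counts Integer matrix (bins x samples).
#' @export
write_bin_counts <- function(counts, genome, path) {
  df <- cbind(genome$bins, as.data.frame(counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample manifest
#'
#' CSV with header exactly
#' `sample_id,batch_id,bmi,karyotype,fetal_sex,protocol,true_ff,control_type`.
#' Validates uniqueness of (sample_id, batch_id) within a protocol arm,
#' positive BMI, `true_ff` in `[0, 1]`, and that control rows carry no
#' karyotype.
#'
#' @param path CSV file.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character",
                                       batch_id = "character",
                                       karyotype = "character",
                                       fetal_sex = "character",
                                       protocol = "character",
                                       control_type = "character"))
  validate_manifest(df)
}

#' @rdname read_manifest
#' @param manifest Data frame to validate or write.
#' @export
validate_manifest <- function(manifest) {
  want <- c("sample_id", "batch_id", "bmi", "karyotype", "fetal_sex",
            "protocol", "true_ff", "control_type")
  if (!identical(names(manifest), want))
    stop(sprintf("manifest header must be exactly: %s", paste(want, collapse = ",")))
  manifest$karyotype[is.na(manifest$karyotype)] <- ""
  key <- paste(manifest$sample_id, manifest$batch_id, manifest$protocol)
  if (anyDuplicated(key))
    stop("duplicate (sample_id, batch_id) within a protocol arm")
  if (any(!is.na(manifest$bmi) & manifest$bmi <= 0)) stop("bmi must be > 0")
  ok_ff <- is.na(manifest$true_ff) |
    (manifest$true_ff >= 0 & manifest$true_ff <= 1)
  if (!all(ok_ff)) stop("true_ff must lie in [0, 1]")
  ctl <- manifest$control_type != "none"
  if (any(ctl & manifest$karyotype != ""))
    stop("control rows must not carry a karyotype")
  manifest
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write region definitions as BED4
#'
#' BED4 (`chrom`, `start`, `end`, `name`), 0-based half-open, scaled
#' coordinates.
#' @param path BED file.
#' @export
read_regions_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("regions BED not found: %s", path))
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stats::setNames(df[, 1:4], c("chrom", "start", "end", "name"))
}

#' @rdname read_regions_bed
#' @param genome An `ffa_genome` whose region table is written.
#' @export
write_regions_bed <- function(genome, path) {
  r <- genome$regions
  utils::write.table(r[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write per-sample-region screening results
#'
#' CSV `sample_id,region,depth_ratio,z_score,ff_positive,call`.
#' @param results Data frame from [screen_cohort()].
#' @param path Output CSV.
#' @export
write_results <- function(results, path) {
  utils::write.csv(
    results[, c("sample_id", "region", "depth_ratio", "z_score",
                "ff_positive", "call")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
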