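# GRCh38 chromosome lengths (bp), used as the shape template for the
# scaled simulation genome. Relative chromosome sizes drive the per-region
# count totals and hence the z-score variance structure.
GRCH38_LENGTHS <- c(
  chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
  chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
  chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
  chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
  chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
  chr21 = 46709983, chr22 = 50818468, chrX = 156040895, chrY = 57227415
)

AUTOSOMES <- paste0("chr", 1:22)
COMMON_ANEUPLOIDY_CHROMS <- c("chr13", "chr18", "chr21")

#' Build the binned simulation genome
#'
#' Constructs a scaled stand-in for the human genome: each chromosome is
#' `1/genome_scale` of its GRCh38 length, partitioned into fixed-width bins
#' (0-based, half-open); trailing partial bins are dropped. The region table
#' contains every whole chromosome (classed as common aneuploidy for
#' chr13/18/21, rare autosomal aneuploidy elsewhere, and sex-chromosome
#' entries for chrX/chrY) plus any configured microdeletion intervals.
#'
#' @param config A run configuration list, see [default_config()]. Uses
#'   `genome_scale`, `bin_width` (scaled bp) and `microdeletions` (named list
#'   of `list(chrom, start, end)` in real bp).
#' @return An object of class `ffa_genome`: chromosomes, bins, region table
#'   (with screening class and hypothesis direction), per-region bin indices,
#'   and an autosomal-bin indicator.
#' @examples
#' g <- build_genome(default_config())
#' g
#' @export
build_genome <- function(config = default_config()) {
  scale <- config$genome_scale
  bw <- config$bin_width
  stopifnot(scale >= 1, bw >= 1)
  lens <- pmax(floor(GRCH38_LENGTHS / scale), bw)

  bin_list <- lapply(names(lens), function(ch) {
    n <- floor(lens[[ch]] / bw)
    data.frame(chrom = rep(ch, n), start = (seq_len(n) - 1L) * bw,
               end = seq_len(n) * bw, stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, bin_list)

  regions <- data.frame(
    name = names(lens), chrom = names(lens), start = 0,
    end = floor(lens / bw) * bw,
    class = ifelse(names(lens) %in% COMMON_ANEUPLOIDY_CHROMS, "common_aneuploidy",
            ifelse(names(lens) == "chrX", "sca_x",
            ifelse(names(lens) == "chrY", "sex", "raa"))),
    direction = ifelse(names(lens) == "chrY", "gain", "gain"),
    stringsAsFactors = FALSE
  )

  for (nm in names(config$microdeletions)) {
    md <- config$microdeletions[[nm]]
    ch <- md$chrom
    if (!ch %in% names(lens))
      stop(sprintf("region '%s': unknown chromosome '%s'", nm, ch))
    s <- floor(md$start / scale); e <- floor(md$end / scale)
    if (s < 0 || e > lens[[ch]])
      stop(sprintf("region '%s' extends outside %s (0-%d)", nm, ch, lens[[ch]]))
    regions <- rbind(regions, data.frame(
      name = nm, chrom = ch, start = s, end = e,
      class = "microdeletion", direction = "loss", stringsAsFactors = FALSE))
  }
  regions$direction[regions$class == "microdeletion"] <- "loss"

  region_bins <- lapply(seq_len(nrow(regions)), function(i) {
    which(bins$chrom == regions$chrom[i] &
          bins$start >= regions$start[i] & bins$end <= regions$end[i])
  })
  names(region_bins) <- regions$name
  empty <- vapply(region_bins, length, 1L) == 0L
  if (any(empty))
    stop(sprintf("region '%s' is not covered by any whole bin",
                 regions$name[which(empty)[1]]))

  g <- list(
    chromosomes = data.frame(name = names(lens), length = unname(lens),
                             stringsAsFactors = FALSE),
    bin_width = bw, genome_scale = scale, bins = bins,
    regions = regions, region_bins = region_bins,
    autosomal = bins$chrom %in% AUTOSOMES,
    n_bins = nrow(bins)
  )
  class(g) <- "ffa_genome"
  g
}

#' @export
print.ffa_genome <- function(x, ...) {
  cat(sprintf("ffa_genome: %d chromosomes (1/%d scale), %d bins of %d bp, %d regions\n",
              nrow(x$chromosomes), x$genome_scale, x$n_bins, x$bin_width,
              nrow(x$regions)))
  invisible(x)
}

#' Bin indices of a named region
#' @param genome An `ffa_genome`.
#' @param region Region name present in `genome$regions$name`.
#' @return Integer vector of row indices into `genome$bins`.
#' @export
region_bin_index <- function(genome, region) {
  idx <- genome$region_bins[[region]]
  if (is.null(idx)) stop(sprintf("region '%s' not in genome", region))
  idx
}
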