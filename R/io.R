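#' Construct a genotype table
#'
#' The central genotype container: a samples x variants matrix of alt-allele
#' dosages in \{0, 1, 2\} with \code{NA} for missing calls, plus per-variant
#' metadata. Missing genotypes are never imputed at I/O time; imputation is
#' an explicit decision of the association scan.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param variant_meta data.frame with columns \code{scaffold},
#'   \code{pos} (1-based bp), \code{ref}, \code{alt}; one row per variant.
#' @param sample_ids character vector of unique sample identifiers.
#' @return an object of class \code{genotype_table}.
#' @export
genotype_table <- function(dosages, variant_meta, sample_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  sample_ids <- as.character(sample_ids)
  stopifnot(!anyDuplicated(sample_ids),
            nrow(variant_meta) == ncol(dosages),
            all(c("scaffold", "pos", "ref", "alt") %in% names(variant_meta)))
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  variant_meta <- as.data.frame(variant_meta, stringsAsFactors = FALSE)
  variant_meta$pos <- as.integer(variant_meta$pos)
  # positions strictly increasing within each scaffold
  for (sc in unique(variant_meta$scaffold)) {
    p <- variant_meta$pos[variant_meta$scaffold == sc]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("variant positions must be strictly increasing within scaffold ", sc)
  }
  if (is.null(variant_meta$id))
    variant_meta$id <- if (nrow(variant_meta) == 0) character(0) else
      paste0(variant_meta$scaffold, ":", variant_meta$pos)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variant_meta$id
  structure(list(dosages = dosages, variant_meta = variant_meta,
                 sample_ids = sample_ids),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$sample_ids), "samples x",
      nrow(x$variant_meta), "variants on",
      length(unique(x$variant_meta$scaffold)), "scaffold(s)\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosages)

#' Subset a genotype table
#'
#' @param x a \code{genotype_table}.
#' @param samples sample ids or indices to keep (default all).
#' @param variants variant indices or logical mask to keep (default all).
#' @return a \code{genotype_table}.
#' @export
subset_genotypes <- function(x, samples = NULL, variants = NULL) {
  d <- x$dosages; vm <- x$variant_meta
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, x$sample_ids)
    if (anyNA(samples)) stop("unknown sample id(s)")
    d <- d[samples, , drop = FALSE]
  }
  if (!is.null(variants)) {
    if (is.logical(variants)) variants <- which(variants)
    variants <- sort(unique(variants))  # keep coordinate order
    d <- d[, variants, drop = FALSE]
    vm <- vm[variants, , drop = FALSE]
  }
  genotype_table(d, vm, rownames(d))
}

#' Target-region interval set
#'
#' Half-open, 0-based intervals (BED convention) describing predicted
#' restriction-digest fragments to which genotyping is confined.
#'
#' @param scaffold,start,end vectors of equal length; \code{start < end},
#'   coordinates non-negative, 0-based half-open.
#' @return data.frame of class \code{target_regions} with a length column.
#' @export
target_regions <- function(scaffold, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(all(start >= 0), all(end > start))
  structure(data.frame(scaffold = as.character(scaffold), start = start,
                       end = end, length = end - start,
                       stringsAsFactors = FALSE),
            class = c("target_regions", "data.frame"))
}

gt_to_dosage <- function(gt) {
  # GT strings to dosage; phased "|" treated as unphased; "." missing
  gt <- sub(":.*", "", gt)
  gt <- gsub("\\|", "/", gt)
  out <- rep(NA_real_, length(gt))
  out[gt == "0/0"] <- 0
  out[gt %in% c("0/1", "1/0")] <- 1
  out[gt == "1/1"] <- 2
  out
}

#' Read a VCF into a genotype table
#'
#' Parses biallelic diploid records; multiallelic sites are excluded and
#' counted (attribute \code{n_multiallelic}). Phased separators are accepted
#' and treated as unphased; missing genotypes become \code{NA} dosages.
#'
#' @param path path to a VCF 4.x file (plain text or gzipped).
#' @param region_filter optional [target_regions()]; keep only variants whose
#'   position falls inside an interval (VCF position p maps to interval
#'   space as p - 1).
#' @return a \code{genotype_table}; attribute \code{n_multiallelic} carries
#'   the count of excluded multiallelic records.
#' @export
read_vcf <- function(path, region_filter = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    gt <- matrix(numeric(0), nrow = 0, ncol = 0)
    tab <- genotype_table(matrix(numeric(0), 1, 0)[0, , drop = FALSE],
                          data.frame(scaffold = character(), pos = integer(),
                                     ref = character(), alt = character()),
                          character(0))
    attr(tab, "n_multiallelic") <- 0L
    return(tab)
  }
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  n_multi <- sum(multi)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field")
  keep <- !multi
  if (!is.null(region_filter)) {
    pos0 <- as.integer(fix$POS) - 1L
    inreg <- logical(nrow(fix))
    for (r in seq_len(nrow(region_filter))) {
      hit <- fix$CHROM == region_filter$scaffold[r] &
        pos0 >= region_filter$start[r] & pos0 < region_filter$end[r]
      inreg <- inreg | hit
    }
    keep <- keep & inreg
  }
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]
  dos <- matrix(gt_to_dosage(gt_raw), nrow = nrow(gt_raw),
                ncol = ncol(gt_raw),
                dimnames = list(NULL, colnames(gt_raw)))
  vm <- data.frame(scaffold = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT,
                   id = ifelse(is.na(fix$ID) | fix$ID == ".",
                               paste0(fix$CHROM, ":", fix$POS), fix$ID),
                   stringsAsFactors = FALSE)
  tab <- genotype_table(t(dos), vm, colnames(gt_raw))
  attr(tab, "n_multiallelic") <- as.integer(n_multi)
  tab
}

#' Write a genotype table as VCF 4.2
#'
#' Emits a GT-only FORMAT with contig header lines for every scaffold
#' present. Round-trips with [read_vcf()] on the dosage matrix.
#'
#' @param table a \code{genotype_table}.
#' @param path output path (plain text).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(table, path) {
  vm <- table$variant_meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines("##source=torporscan", con)
  for (sc in unique(vm$scaffold))
    writeLines(sprintf("##contig=<ID=%s>", sc), con)
  writeLines('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">', con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", table$sample_ids), collapse = "\t"), con)
  if (nrow(vm) > 0) {
    gt_strings <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
    for (j in seq_len(nrow(vm))) {
      g <- table$dosages[, j]
      cells <- ifelse(is.na(g), "./.", gt_strings[as.character(g)])
      writeLines(paste(c(vm$scaffold[j], vm$pos[j], vm$id[j], vm$ref[j],
                         vm$alt[j], ".", "PASS", ".", "GT", cells),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}

.schemas <- list(
  phenotype = c("sample", "onset_day", "sex", "year", "placement_day",
                "age_class", "mass", "implant_day"),
  telemetry = c("sample", "timestamp", "temp_c"),
  expression = c("tag", "scaffold", "position")
)

#' Read a typed TSV/BED table
#'
#' @param path file path. TSVs must carry a header; \code{regions} is BED3
#'   (headerless, whitespace-separated, 0-based half-open).
#' @param schema one of \code{"phenotype"}, \code{"telemetry"},
#'   \code{"expression"}, \code{"regions"}.
#' @return a typed data.frame ([target_regions()] for \code{regions});
#'   telemetry records are sorted by timestamp with a warning if the file
#'   was out of order.
#' @export
read_table_typed <- function(path, schema = c("phenotype", "telemetry",
                                              "expression", "regions")) {
  schema <- match.arg(schema)
  if (schema == "regions") {
    raw <- read.delim(path, header = FALSE, sep = "",
                      stringsAsFactors = FALSE)
    if (ncol(raw) < 3) stop("BED file needs at least 3 columns")
    return(target_regions(raw[[1]], raw[[2]], raw[[3]]))
  }
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- .schemas[[schema]]
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (schema == "phenotype") {
    if (anyDuplicated(d$sample)) stop("duplicate sample rows in phenotype sheet")
    for (cc in c("onset_day", "placement_day", "implant_day"))
      d[[cc]] <- check_numeric_col(d[[cc]], cc)
    d$mass <- check_numeric_col(d$mass, "mass")
  } else if (schema == "telemetry") {
    d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC")
    if (anyNA(d$timestamp)) stop("unparseable timestamp in telemetry table")
    d$temp_c <- check_numeric_col(d$temp_c, "temp_c")
    if (is.unsorted(d$timestamp)) {
      warning("telemetry timestamps out of order; sorting by time")
      d <- d[order(d$timestamp), , drop = FALSE]
      rownames(d) <- NULL
    }
  } else if (schema == "expression") {
    d$position <- check_numeric_col(d$position, "position")
  }
  d
}

check_numeric_col <- function(x, name) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & x != "" & x != "NA" & is.na(out))
  if (length(bad)) stop("unparseable value in column '", name,
                        "' at row ", bad[1])
  out
}
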