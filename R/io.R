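#' Read a GenAlEx codominant genotype file
#'
#' Parses the GenAlEx codominant CSV layout: row 1 gives `n_loci, n_samples,
#' n_pops, pop sizes...`; row 2 a dataset title followed by population names;
#' row 3 the column header (`Sample`, `Pop`, then two columns per locus, the
#' locus name over the first of each pair); data rows follow with `0` coding
#' a missing allele. The parser is strict: header counts that disagree with
#' the data are reported with the offending row.
#'
#' @param path path to a GenAlEx CSV file
#' @return a [genotype_table()] with population labels from the `Pop` column
#' @export
read_genalex <- function(path) {
  raw <- readLines(path, warn = FALSE)
  if (length(raw) < 3L) stop("GenAlEx file must have at least 3 header rows")
  split_csv <- function(x) {
    # keep trailing empty fields (strsplit drops them)
    out <- strsplit(paste0(x, ","), ",", fixed = TRUE)[[1]]
    trimws(out)
  }
  r1 <- split_csv(raw[1])
  n_loci <- suppressWarnings(as.integer(r1[1]))
  n_samp <- suppressWarnings(as.integer(r1[2]))
  n_pops <- suppressWarnings(as.integer(r1[3]))
  if (any(is.na(c(n_loci, n_samp, n_pops))))
    stop("row 1: expected integer n_loci, n_samples, n_pops")
  hdr <- split_csv(raw[3])
  allele_cols <- length(hdr) - 2L
  if (allele_cols != 2L * n_loci)
    stop(sprintf(
      "row 3: %d allele columns found but header declares %d loci (need %d)",
      allele_cols, n_loci, 2L * n_loci))
  loci <- hdr[seq(3L, by = 2L, length.out = n_loci)]
  loci[loci == ""] <- paste0("L", which(loci == ""))
  data_rows <- raw[-(1:3)]
  data_rows <- data_rows[trimws(gsub(",", "", data_rows)) != ""]
  if (length(data_rows) != n_samp)
    stop(sprintf(
      "header declares %d samples but %d data rows found (first data row is file row 4)",
      n_samp, length(data_rows)))
  ids <- character(n_samp)
  pops <- character(n_samp)
  a1 <- matrix(NA_integer_, n_samp, n_loci)
  a2 <- matrix(NA_integer_, n_samp, n_loci)
  for (i in seq_len(n_samp)) {
    f <- split_csv(data_rows[i])
    if (length(f) < 2L + 2L * n_loci)
      stop(sprintf("file row %d: expected %d fields, found %d",
                   i + 3L, 2L + 2L * n_loci, length(f)))
    ids[i] <- f[1]
    pops[i] <- f[2]
    al <- suppressWarnings(as.integer(f[3:(2L + 2L * n_loci)]))
    if (anyNA(al))
      stop(sprintf("file row %d: non-integer allele code", i + 3L))
    x <- al[seq(1L, by = 2L, length.out = n_loci)]
    y <- al[seq(2L, by = 2L, length.out = n_loci)]
    half <- xor(x == 0L, y == 0L)
    if (any(half))
      stop(sprintf("file row %d: half-missing genotype (one allele 0)",
                   i + 3L))
    x[x == 0L] <- NA_integer_
    y[y == 0L] <- NA_integer_
    a1[i, ] <- x
    a2[i, ] <- y
  }
  rownames(a1) <- rownames(a2) <- ids
  colnames(a1) <- colnames(a2) <- loci
  meta <- data.frame(id = ids, pop = pops, class = "reference",
                     stringsAsFactors = FALSE)
  meta$pop[meta$pop == ""] <- NA_character_
  genotype_table(a1, a2, meta)
}

#' Write a genotype table in the GenAlEx codominant dialect
#'
#' Missing genotypes are written as `0,0`. Only the sample ID, population
#' label and calls survive this dialect; use the TSV writer to keep class,
#' coordinates and lineage.
#'
#' @param x a [genotype_table()]
#' @param path output path
#' @param title dataset title placed in row 2
#' @export
write_genalex <- function(x, path, title = "pangotrace export") {
  pops <- x$meta$pop
  pops[is.na(pops)] <- ""
  pop_levels <- unique(pops)
  sizes <- as.integer(table(factor(pops, levels = pop_levels)))
  loci <- loci_names(x)
  r1 <- paste(c(n_loci(x), n_ind(x), length(pop_levels), sizes),
              collapse = ",")
  r2 <- paste(c(title, "", "", pop_levels), collapse = ",")
  locus_hdr <- as.vector(rbind(loci, ""))
  r3 <- paste(c("Sample", "Pop", locus_hdr), collapse = ",")
  lines <- c(r1, r2, r3)
  a1 <- x$a1; a2 <- x$a2
  a1[is.na(a1)] <- 0L
  a2[is.na(a2)] <- 0L
  body <- vapply(seq_len(n_ind(x)), function(i) {
    paste(c(sample_ids(x)[i], pops[i],
            as.vector(rbind(a1[i, ], a2[i, ]))), collapse = ",")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read/write the canonical long-format TSV
#'
#' One row per (sample, locus) with columns `sample, population, class, lon,
#' lat, locus, allele1, allele2`; missing alleles are empty fields. This
#' dialect is lossless for all metadata the package carries except generator
#' truth columns.
#'
#' @param path file path
#' @return a [genotype_table()]
#' @export
read_msat_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "",
                         colClasses = list(sample = "character",
                                           locus = "character"))
  need <- c("sample", "population", "class", "lon", "lat", "locus",
            "allele1", "allele2")
  if (!all(need %in% names(d)))
    stop("TSV must have columns: ", paste(need, collapse = ", "))
  ids <- unique(d$sample)
  loci <- unique(d$locus)
  a1 <- matrix(NA_integer_, length(ids), length(loci),
               dimnames = list(ids, loci))
  a2 <- a1
  ii <- match(d$sample, ids)
  jj <- match(d$locus, loci)
  a1[cbind(ii, jj)] <- as.integer(d$allele1)
  a2[cbind(ii, jj)] <- as.integer(d$allele2)
  first <- !duplicated(d$sample)
  meta <- data.frame(id = d$sample[first], pop = d$population[first],
                     class = d$class[first], lon = d$lon[first],
                     lat = d$lat[first], stringsAsFactors = FALSE)
  genotype_table(a1, a2, meta)
}

#' @rdname read_msat_tsv
#' @param x a [genotype_table()]
#' @export
write_msat_tsv <- function(x, path) {
  ids <- sample_ids(x)
  loci <- loci_names(x)
  grid <- expand.grid(j = seq_along(loci), i = seq_along(ids))
  d <- data.frame(
    sample = ids[grid$i],
    population = x$meta$pop[grid$i],
    class = x$meta$class[grid$i],
    lon = x$meta$lon[grid$i],
    lat = x$meta$lat[grid$i],
    locus = loci[grid$j],
    allele1 = x$a1[cbind(grid$i, grid$j)],
    allele2 = x$a2[cbind(grid$i, grid$j)],
    stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
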