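#' Build a marker map
#'
#' Validates and sorts a marker map. Positions are 1-based physical
#' coordinates; markers are sorted by (chromosome, position) on ingest and
#' must be unique by id and by position within a chromosome.
#'
#' @param marker_id character vector of unique marker names.
#' @param chrom chromosome labels (character or coercible).
#' @param pos_bp integer base-pair positions, 1-based.
#' @param cM optional genetic positions in centimorgans.
#' @return A `data.frame` with class `c("marker_map", "data.frame")`, sorted
#'   by chromosome then position.
#' @export
marker_map <- function(marker_id, chrom, pos_bp, cM = NULL) {
  marker_id <- as.character(marker_id)
  chrom <- as.character(chrom)
  pos_bp <- as.numeric(pos_bp)
  if (anyDuplicated(marker_id))
    stop("marker ids must be unique")
  if (length(marker_id) != length(chrom) || length(chrom) != length(pos_bp))
    stop("marker map fields must have equal length")
  map <- data.frame(marker_id = marker_id, chrom = chrom, pos_bp = pos_bp,
                    stringsAsFactors = FALSE)
  if (!is.null(cM)) map$cM <- as.numeric(cM)
  ord <- order(map$chrom, map$pos_bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Construct a genotype matrix container
#'
#' The central container of the pipeline: an individuals x markers matrix of
#' minor-allele dosages (0, 1, 2, with `NA` for missing) together with
#' individual metadata (id, breed label) and a [marker_map()].
#'
#' @param geno integer matrix, individuals in rows, markers in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param individuals `data.frame` with columns `individual_id` and `breed`
#'   (and optionally `sex`).
#' @param map a [marker_map()] whose rows match the columns of `geno`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, individuals, map) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(individuals))
    stop("genotype rows (", nrow(geno), ") != individuals (",
         nrow(individuals), ")")
  if (ncol(geno) != nrow(map))
    stop("genotype columns (", ncol(geno), ") != markers in map (",
         nrow(map), ")")
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(individuals$individual_id))
    stop("individual ids must be unique")
  rownames(geno) <- individuals$individual_id
  colnames(geno) <- map$marker_id
  structure(list(geno = geno,
                 individuals = as.data.frame(individuals),
                 map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$geno), "individuals x", ncol(x$geno),
      "markers;", length(unique(x$individuals$breed)), "breeds;",
      length(unique(x$map$chrom)), "chromosomes\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Construct a phased haplotype panel
#'
#' Each individual contributes exactly two rows (haplotype copies 1 and 2);
#' the two copies of an individual must sum to its diploid genotype wherever
#' the genotype is non-missing.
#'
#' @param haps 0/1 matrix, `2 * n_individuals` rows, markers in columns.
#' @param individual_id character vector of length `nrow(haps)` giving the
#'   individual owning each row.
#' @param copy integer vector (1 or 2), which haplotype copy each row is.
#' @param map a [marker_map()].
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(haps, individual_id, copy, map) {
  haps <- as.matrix(haps)
  storage.mode(haps) <- "integer"
  if (ncol(haps) != nrow(map)) stop("haplotype columns != markers in map")
  if (length(individual_id) != nrow(haps) || length(copy) != nrow(haps))
    stop("phase bookkeeping length mismatch")
  tab <- table(individual_id)
  if (any(tab != 2L)) stop("each individual must contribute exactly two rows")
  structure(list(haps = haps,
                 phase_of = data.frame(individual_id = as.character(individual_id),
                                       copy = as.integer(copy),
                                       stringsAsFactors = FALSE),
                 map = map),
            class = "haplotype_panel")
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' Alleles are recoded per marker so that the dosage counts the minor allele
#' (the major allele is the reference); "0 0" is parsed as missing. The breed
#' label is taken from the family-ID column, following the community
#' convention of storing cohort labels there.
#'
#' @param ped_path path to the .ped file (6 leading columns, then two allele
#'   columns per marker).
#' @param map_path path to the .map file (chrom, marker id, cM, bp).
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)
  mp <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "marker_id", "cM", "pos_bp"))
  m <- nrow(mp)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  if (n == 0L) stop("empty ped file: ", ped_path)
  a1 <- matrix("", n, m)
  a2 <- matrix("", n, m)
  fam <- character(n); iid <- character(n); sex <- integer(n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6L + 2L * m)
      stop("ped line ", i, ": expected ", 6L + 2L * m, " fields, found ",
           length(tok))
    fam[i] <- tok[1]; iid[i] <- tok[2]; sex[i] <- suppressWarnings(as.integer(tok[5]))
    al <- tok[-(1:6)]
    a1[i, ] <- al[seq(1L, 2L * m, by = 2L)]
    a2[i, ] <- al[seq(2L, 2L * m, by = 2L)]
  }
  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    alleles <- c(x1[!miss], x2[!miss])
    if (length(alleles) == 0L) next
    tab <- sort(table(alleles), decreasing = TRUE)
    # major allele = most frequent; ties broken alphabetically by sort order
    major <- names(tab)[1]
    g <- (x1 != major) + (x2 != major)
    g[miss] <- NA_integer_
    geno[, j] <- g
  }
  map <- marker_map(mp$marker_id, mp$chrom, mp$pos_bp, cM = mp$cM)
  # marker_map() may reorder; apply the same ordering to genotype columns
  ord <- match(map$marker_id, mp$marker_id)
  geno <- geno[, ord, drop = FALSE]
  genotype_matrix(geno,
                  data.frame(individual_id = iid, breed = fam, sex = sex,
                             stringsAsFactors = FALSE),
                  map)
}

#' Write PLINK text genotypes
#'
#' Inverse of [read_plink()] up to allele labels: dosage 0 is written as the
#' homozygous "A A" reference genotype, 2 as "B B", 1 as "A B", missing as
#' "0 0".
#'
#' @param gm a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @export
write_plink <- function(gm, ped_path, map_path) {
  map <- gm$map
  cM <- if ("cM" %in% names(map)) map$cM else rep(0, nrow(map))
  utils::write.table(data.frame(map$chrom, map$marker_id, cM, map$pos_bp),
                     map_path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  g <- gm$geno
  n <- nrow(g); m <- ncol(g)
  al1 <- matrix("A", n, m); al2 <- matrix("A", n, m)
  al1[g == 2L] <- "B"; al2[g >= 1L] <- "B"
  al1[is.na(g)] <- "0"; al2[is.na(g)] <- "0"
  body <- vapply(seq_len(n), function(i) {
    paste(as.vector(rbind(al1[i, ], al2[i, ])), collapse = " ")
  }, character(1))
  ind <- gm$individuals
  sex <- if ("sex" %in% names(ind)) ind$sex else rep(0L, n)
  lead <- paste(ind$breed, ind$individual_id, 0, 0, sex, -9)
  writeLines(paste(lead, body), ped_path)
}

#' Read a phenotype table
#'
#' Expects a TSV with header columns `individual_id`, `breed`, `trait`,
#' `value` and optionally `age_years`. Values of "NA" are dropped with a
#' warning; any other non-numeric value is an error naming the row.
#'
#' @param tsv_path path to the phenotype TSV.
#' @return `data.frame` with one record per (individual, trait).
#' @export
read_phenotypes <- function(tsv_path) {
  if (!file.exists(tsv_path)) stop("phenotype file not found: ", tsv_path)
  df <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("individual_id", "breed", "trait", "value")
  if (!all(need %in% names(df)))
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) {
    out <- data.frame(individual_id = character(), breed = character(),
                      trait = character(), value = numeric(),
                      age_years = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  na_rows <- df$value == "NA" | is.na(df$value)
  if (any(na_rows)) {
    warning(sum(na_rows), " record(s) with value NA dropped")
    df <- df[!na_rows, , drop = FALSE]
  }
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val)) {
    bad <- which(is.na(val))[1]
    stop("non-numeric phenotype value at data row ", bad, ": '",
         df$value[bad], "'")
  }
  key <- paste(df$individual_id, df$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (individual_id, trait) record: ",
         sub("\r", " / ", key[duplicated(key)][1]))
  age <- if ("age_years" %in% names(df))
    suppressWarnings(as.numeric(df$age_years)) else rep(NA_real_, nrow(df))
  data.frame(individual_id = df$individual_id, breed = df$breed,
             trait = df$trait, value = val, age_years = age,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a phenotype table (TSV)
#' @param phenos phenotype `data.frame` as returned by [read_phenotypes()].
#' @param tsv_path output path.
#' @export
write_phenotypes <- function(phenos, tsv_path) {
  utils::write.table(phenos, tsv_path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
}

#' Write autozygous segments as BED
#'
#' Internal coordinates are 1-based inclusive; BED output is 0-based
#' half-open. The name column carries the individual id. Output is sorted by
#' (chromosome, start) regardless of input order.
#'
#' @param segments `data.frame` with columns `individual_id`, `chrom`,
#'   `start_bp`, `end_bp` (1-based inclusive).
#' @param path output BED path.
#' @export
write_segments_bed <- function(segments, path) {
  if (nrow(segments) == 0L) {
    writeLines(character(0), path)
    return(invisible(NULL))
  }
  if (any(segments$end_bp <= segments$start_bp))
    stop("segment end must exceed start")
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start_bp - 1L,
                    end = segments$end_bp,
                    name = segments$individual_id)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Write an association result table (TSV)
#'
#' @param assoc association `data.frame` (columns `marker_id`, `chrom`,
#'   `pos_bp`, `stat`, `p_value`, `method`, ...).
#' @param path output path.
#' @export
write_association_tsv <- function(assoc, path) {
  utils::write.table(assoc, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
}

# Per-marker minor-allele frequency over non-missing calls.
#' Per-marker allele frequency and missingness
#'
#' @param gm a [genotype_matrix()].
#' @return `data.frame` with columns `marker_id`, `freq` (frequency of the
#'   dosage-counted allele), `maf`, `missing_rate`, `n_called`.
#' @export
marker_freq <- function(gm) {
  g <- gm$geno
  n_called <- colSums(!is.na(g))
  freq <- colSums(g, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  freq[n_called == 0L] <- NA_real_
  data.frame(marker_id = gm$map$marker_id,
             freq = freq,
             maf = pmin(freq, 1 - freq),
             missing_rate = 1 - n_called / nrow(g),
             n_called = n_called,
             row.names = NULL)
}

#' Per-breed allele frequencies
#'
#' @param gm a [genotype_matrix()].
#' @return breeds x markers matrix of allele frequencies (frequency of the
#'   dosage-counted allele), computed complete-case per (breed, marker).
#' @export
breed_freqs <- function(gm) {
  g <- gm$geno
  breeds <- gm$individuals$breed
  ub <- sort(unique(breeds))
  f <- matrix(NA_real_, length(ub), ncol(g),
              dimnames = list(ub, colnames(g)))
  for (b in ub) {
    sub <- g[breeds == b, , drop = FALSE]
    nc <- colSums(!is.na(sub))
    fb <- colSums(sub, na.rm = TRUE) / (2 * pmax(nc, 1L))
    fb[nc == 0L] <- NA_real_
    f[b, ] <- fb
  }
  f
}

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param individuals optional individual ids or logical/integer row index.
#' @param markers optional marker ids or logical/integer column index.
#' @return A [genotype_matrix()] restricted to the selection.
#' @export
subset_genotypes <- function(gm, individuals = NULL, markers = NULL) {
  ri <- seq_len(nrow(gm$geno))
  if (!is.null(individuals)) {
    if (is.character(individuals)) {
      ri <- match(individuals, gm$individuals$individual_id)
      if (anyNA(ri))
        stop("unknown individual id(s): ",
             paste(individuals[is.na(ri)], collapse = ", "))
    } else if (is.logical(individuals)) {
      ri <- which(individuals)
    } else {
      ri <- as.integer(individuals)
    }
  }
  ci <- seq_len(ncol(gm$geno))
  if (!is.null(markers)) {
    ci <- if (is.character(markers)) match(markers, gm$map$marker_id)
          else if (is.logical(markers)) which(markers) else as.integer(markers)
    if (anyNA(ci)) stop("unknown marker selection")
  }
  map <- gm$map[ci, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  genotype_matrix(gm$geno[ri, ci, drop = FALSE],
                  gm$individuals[ri, , drop = FALSE], map)
}
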