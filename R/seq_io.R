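#' Read a regulatory-module analysis set
#'
#' Loads the three standard inputs of the pipeline: module sequences from
#' FASTA, binding-site annotations from BED6+1, and position weight matrices
#' from a JASPAR-style matrix file, and validates that they are mutually
#' consistent (every site interval lies within its module; every factor name
#' resolves to a motif).
#'
#' @param fasta_path FASTA file of module sequences. The record id is the
#'   module id; an optional description of the form `chrom:start-end` carries
#'   genomic coordinates (0-based half-open), otherwise `chrom` defaults to
#'   the module id with `start = 0`.
#' @param bed_path BED6+1 file: chrom, start, end, name (= factor), score
#'   (ignored), strand, and a 7th column with the module id.
#' @param motif_path JASPAR-format matrix file (counts or frequencies).
#' @param background optional [background()] used to weight motif
#'   pseudocounts.
#' @return list with `modules` (data.frame: `id`, `chrom`, `start`, `end`,
#'   `sequence`), `annotations` (data.frame: `module_id`, `chrom`, `start`,
#'   `end`, `strand`, `factor`), and `motifs` (named list of [motif()]
#'   objects).
#' @export
read_regulatory_set <- function(fasta_path, bed_path, motif_path,
                                background = NULL) {
  modules <- read_modules(fasta_path)
  annotations <- read_sites(bed_path)
  motifs <- read_motifs(motif_path, background = background)
  miss <- setdiff(annotations$factor, names(motifs))
  if (length(miss))
    stop("no motif for factor(s): ", paste(miss, collapse = ", "))
  .check_sites_in_modules(modules, annotations)
  list(modules = modules, annotations = annotations, motifs = motifs)
}

.check_sites_in_modules <- function(modules, annotations) {
  idx <- match(annotations$module_id, modules$id)
  if (anyNA(idx))
    stop("site(s) reference unknown module(s): ",
         paste(unique(annotations$module_id[is.na(idx)]), collapse = ", "))
  bad <- annotations$chrom != modules$chrom[idx] |
    annotations$start < modules$start[idx] |
    annotations$end > modules$end[idx] |
    annotations$end <= annotations$start
  if (any(bad))
    stop("site interval(s) outside their module: rows ",
         paste(which(bad), collapse = ", "))
  invisible(TRUE)
}

#' Read module sequences from FASTA
#'
#' @param path FASTA file; record id = module id, optional description
#'   `chrom:start-end` (0-based half-open).
#' @return data.frame with `id`, `chrom`, `start`, `end`, `sequence`.
#' @export
read_modules <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- names(x)
  id <- sub("\\s.*$", "", nm)
  desc <- ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
  coord <- regmatches(desc, regexec("^(\\S+):(\\d+)-(\\d+)$", desc))
  chrom <- id
  start <- rep(0L, length(x))
  for (i in seq_along(coord)) {
    if (length(coord[[i]]) == 4L) {
      chrom[i] <- coord[[i]][2]
      start[i] <- as.integer(coord[[i]][3])
    }
  }
  data.frame(id = id, chrom = chrom, start = start,
             end = start + Biostrings::width(x),
             sequence = as.character(x), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write module sequences to FASTA
#'
#' Inverse of [read_modules()]: headers are `id chrom:start-end`.
#' @param modules data.frame as returned by [read_modules()].
#' @param path output file.
#' @export
write_modules <- function(modules, path) {
  x <- Biostrings::DNAStringSet(modules$sequence)
  names(x) <- sprintf("%s %s:%d-%d", modules$id, modules$chrom,
                      modules$start, modules$end)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read binding-site annotations from BED6+1
#'
#' @param path BED file with columns chrom, start, end, name (factor), score,
#'   strand, module_id.
#' @return data.frame with `module_id`, `chrom`, `start`, `end`, `strand`,
#'   `factor`.
#' @export
read_sites <- function(path) {
  b <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(b) < 7L) stop("expected BED6+1 (7 columns), got ", ncol(b))
  if (!all(b[[6]] %in% c("+", "-")))
    stop("strand column must be + or -")
  data.frame(module_id = as.character(b[[7]]), chrom = as.character(b[[1]]),
             start = as.integer(b[[2]]), end = as.integer(b[[3]]),
             strand = b[[6]], factor = as.character(b[[4]]),
             stringsAsFactors = FALSE)
}

#' Write binding-site annotations to BED6+1
#' @param annotations data.frame as returned by [read_sites()].
#' @param path output file.
#' @export
write_sites <- function(annotations, path) {
  out <- data.frame(annotations$chrom, annotations$start, annotations$end,
                    annotations$factor, 0L, annotations$strand,
                    annotations$module_id)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read position weight matrices in JASPAR text format
#'
#' Parses records of the form
#' \preformatted{>name
#' A [ 1 2 3 ]
#' C [ 0 1 0 ]
#' G [ 2 0 1 ]
#' T [ 1 1 0 ]}
#' (brackets optional). Counts are kept on the motif object; frequencies are
#' derived with the standard pseudocount (see [motif()]).
#'
#' @param path matrix file.
#' @param background optional [background()] weighting the pseudocount.
#' @param pseudocount passed to [motif()].
#' @return named list of [motif()] objects (each also carrying `counts`).
#' @export
read_motifs <- function(path, background = NULL, pseudocount = 0.5) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif records found in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    name <- trimws(sub("^>\\s*", "", lines[starts[i]]))
    name <- sub("\\s.*$", "", name)
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    body <- lines[(starts[i] + 1):to]
    if (length(body) != 4L)
      stop("malformed matrix for motif ", name, ": expected 4 rows")
    rows <- list()
    for (ln in body) {
      base <- toupper(substr(trimws(ln), 1, 1))
      if (!base %in% DNA_BASES)
        stop("malformed matrix row for motif ", name, ": ", ln)
      nums <- gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", trimws(ln)))
      v <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (anyNA(v)) stop("malformed matrix row for motif ", name, ": ", ln)
      rows[[base]] <- v
    }
    if (length(unique(lengths(rows))) != 1L)
      stop("malformed matrix for motif ", name, ": ragged rows")
    counts <- t(do.call(rbind, rows[DNA_BASES]))  # L x 4
    m <- motif(counts, name = name, background = background,
               pseudocount = pseudocount)
    m$counts <- counts
    out[[name]] <- m
  }
  out
}

#' Write motifs in JASPAR text format
#'
#' Writes the stored count matrix when present, otherwise the frequency
#' matrix, at full precision so that a read/write cycle round-trips.
#' @param motifs named list of [motif()] objects.
#' @param path output file.
#' @export
write_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    mat <- m$counts %||% m$freq
    writeLines(paste0(">", m$name), con)
    for (a in 1:4)
      writeLines(paste0(DNA_BASES[a], " [ ",
                        paste(format(mat[, a], digits = 15, trim = TRUE),
                              collapse = " "), " ]"), con)
  }
  invisible(path)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# module-wide composition (constructor aliased to dodge argument shadowing)
.module_background <- function(sq) background(sq, dinucleotide = FALSE)

#' Extract motif-length, motif-oriented site sequences
#'
#' Returns one sequence of exactly the motif length per annotation, oriented
#' along the motif (minus-strand sites are reverse-complemented). When the
#' annotated footprint length differs from the motif length L, the returned
#' window is the gapless length-L window overlapping the annotation that
#' maximises the information-based fitness F(a) under the motif's landscape
#' (longer footprints are cut, shorter ones extended with flanking
#' nucleotides so that binding affinity is maximal); genomic-leftmost wins
#' ties. Windows containing an ambiguous symbol are disqualified. Annotations
#' whose module cannot supply a valid window are skipped with a warning.
#'
#' @param modules data.frame from [read_modules()].
#' @param annotations data.frame from [read_sites()].
#' @param motifs named list of [motif()] objects keyed by factor.
#' @param background optional [background()] for the fitness landscape;
#'   default: per-module composition.
#' @return data.frame: annotation columns plus `window_start`, `window_end`
#'   (genomic, 0-based half-open) and `sequence` (length exactly the motif
#'   length, motif orientation).
#' @export
extract_site_sequences <- function(modules, annotations, motifs,
                                   background = NULL) {
  .check_sites_in_modules(modules, annotations)
  midx <- match(annotations$module_id, modules$id)
  out <- NULL
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, ]
    mod <- modules[midx[i], ]
    mot <- motifs[[ann$factor]]
    if (is.null(mot)) stop("no motif for factor ", ann$factor)
    L <- mot$length
    rel_s <- ann$start - mod$start   # 0-based within module
    rel_e <- ann$end - mod$start
    n <- nchar(mod$sequence)
    if (rel_e - rel_s == L) {
      w <- rel_s
      sq <- substr(mod$sequence, w + 1, w + L)
      if (ann$strand == "-") sq <- .revcomp(sq)
      if (grepl("N", sq, fixed = TRUE)) {
        warning("site ", i, ": ambiguous bases, skipped")
        next
      }
    } else {
      bg <- background %||% .module_background(mod$sequence)
      land <- build_fitness(mot, bg)
      cand <- seq(max(0L, rel_s - L + 1L), min(n - L, rel_e - 1L))
      if (!length(cand)) {
        warning("site ", i, ": module too short for a length-", L,
                " window, skipped")
        next
      }
      best_w <- NA_integer_; best_F <- -Inf; best_sq <- NULL
      for (w in cand) {
        sq <- substr(mod$sequence, w + 1, w + L)
        if (grepl("N", sq, fixed = TRUE)) next
        if (ann$strand == "-") sq <- .revcomp(sq)
        Fv <- site_fitness(land, sq)
        if (Fv > best_F + 1e-12) { best_F <- Fv; best_w <- w; best_sq <- sq }
      }
      if (is.na(best_w)) {
        warning("site ", i, ": no valid window, skipped")
        next
      }
      w <- best_w; sq <- best_sq
    }
    out <- rbind(out, data.frame(
      module_id = ann$module_id, chrom = ann$chrom,
      start = ann$start, end = ann$end, strand = ann$strand,
      factor = ann$factor,
      window_start = mod$start + w, window_end = mod$start + w + L,
      sequence = sq, stringsAsFactors = FALSE))
  }
  out
}

#' Curate binding-site annotations
#'
#' Applies the three bias-avoiding filters to an annotation set:
#' (i) keep only factors that occur in at least two different modules, so no
#' position weight matrix is dominated by a single module's context;
#' (ii) drop every site that overlaps another site in the set (both members
#' of an overlapping pair are removed), since the fitness landscapes describe
#' selection for a single function; (iii) drop sites on the X chromosome,
#' whose elevated duplication and repeat content would bias the analysis.
#' The filters are iterated to a fixed point, which makes the operation
#' idempotent; row order is preserved.
#'
#' @param annotations data.frame from [read_sites()].
#' @param x_chrom chromosome names treated as X (default `c("chrX", "X")`).
#' @return the curated annotation data.frame (possibly empty).
#' @export
curate_sites <- function(annotations, x_chrom = c("chrX", "X")) {
  a <- annotations
  repeat {
    n_before <- nrow(a)
    if (n_before == 0L) break
    # (i) factor in >= 2 modules
    nmod <- tapply(a$module_id, a$factor, function(x) length(unique(x)))
    a <- a[nmod[a$factor] >= 2L, , drop = FALSE]
    # (ii) no overlap with any other site (same chromosome)
    if (nrow(a) > 0L) {
      keep <- rep(TRUE, nrow(a))
      for (i in seq_len(nrow(a))) {
        ov <- a$chrom == a$chrom[i] &
          a$start < a$end[i] & a$end > a$start[i]
        if (sum(ov) > 1L) keep[i] <- FALSE
      }
      a <- a[keep, , drop = FALSE]
    }
    # (iii) exclude X chromosome
    a <- a[!a$chrom %in% x_chrom, , drop = FALSE]
    if (nrow(a) == n_before) break
  }
  rownames(a) <- NULL
  a
}

#' Local background around a binding site
#'
#' Estimates nucleotide and dinucleotide frequencies from the `flank_bp`
#' base pairs on each side of a site (the site itself excluded), truncated at
#' module edges, with a uniform pseudocount. When both flanks are empty after
#' truncation, falls back to module-wide frequencies with a warning.
#'
#' @param module one row of a [read_modules()] data.frame.
#' @param site one row of a [read_sites()] data.frame (same module).
#' @param flank_bp flank width per side in bp (default 1000).
#' @return a [background()] object.
#' @export
local_background <- function(module, site, flank_bp = 1000) {
  stopifnot(flank_bp > 0)
  rel_s <- site$start - module$start
  rel_e <- site$end - module$start
  n <- nchar(module$sequence)
  left <- substr(module$sequence, max(1, rel_s - flank_bp + 1), rel_s)
  right <- substr(module$sequence, rel_e + 1, min(n, rel_e + flank_bp))
  flanks <- c(left, right)
  flanks <- flanks[nzchar(flanks)]
  if (!length(flanks)) {
    warning("empty flanks after truncation; using module-wide background")
    flanks <- module$sequence
  }
  background(flanks, dinucleotide = TRUE)
}
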