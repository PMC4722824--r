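# Data model and I/O: sequence alignments, microsatellite genotypes,
# population maps, and the combined multilocus dataset.

DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Sequence alignment container
#'
#' A rectangular nucleotide alignment over the alphabet \{A,C,G,T,N,-\}.
#'
#' @param ids character vector of unique individual identifiers.
#' @param seqs character matrix (individuals x sites) of single upper-case
#'   symbols, or a character vector of equal-length sequence strings.
#' @return An object of class `seq_alignment` with elements `ids`, `seqs`
#'   (character matrix) and `length` (number of sites).
#' @export
seq_alignment <- function(ids, seqs) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("alignment error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    }
    seqs <- do.call(rbind, strsplit(toupper(seqs), ""))
  }
  seqs <- toupper(seqs)
  ids <- as.character(ids)
  if (length(ids) != nrow(seqs)) stop("ids/seqs dimension mismatch")
  if (anyDuplicated(ids)) {
    stop("alignment error: duplicated ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad <- !(seqs %in% DNA_ALPHABET)
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(seqs)), arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error: illegal symbol '%s' in record '%s' at position %d",
                 seqs[idx[1L], idx[2L]], ids[idx[1L]], idx[2L]))
  }
  rownames(seqs) <- ids
  structure(list(ids = ids, seqs = seqs, length = ncol(seqs)),
            class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat(sprintf("<seq_alignment> %d sequences x %d bp\n",
              length(x$ids), x$length))
  invisible(x)
}

#' Read a FASTA alignment
#'
#' Reads pre-aligned sequences (via ape) and validates the alignment
#' invariants: equal lengths, unique ids, alphabet restricted to
#' \{A,C,G,T,N,-\}. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return A [seq_alignment()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("parse error: no FASTA records in ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) > 1L) {
    stop("alignment error: ragged FASTA (lengths ",
         paste(unique(lens), collapse = ", "), ") in ", path)
  }
  chars <- toupper(do.call(rbind, as.character(dna)))
  chars[chars == "?"] <- "N"
  seq_alignment(names(dna), chars)
}

#' Write a FASTA alignment
#'
#' @param aln a [seq_alignment()].
#' @param path output path.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "seq_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    writeLines(c(paste0(">", aln$ids[i]),
                 paste(aln$seqs[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Subset an alignment by individual ids
#' @param aln a [seq_alignment()].
#' @param ids ids to keep (order respected).
#' @export
subset_alignment <- function(aln, ids) {
  miss <- setdiff(ids, aln$ids)
  if (length(miss)) stop("unknown ids: ", paste(miss, collapse = ", "))
  seqs <- aln$seqs[match(ids, aln$ids), , drop = FALSE]
  # rows come from a validated alignment: no revalidation needed
  structure(list(ids = as.character(ids), seqs = seqs, length = ncol(seqs)),
            class = "seq_alignment")
}

#' Microsatellite genotype container
#'
#' Diploid allele calls in repeat units; missing genotypes are NA in both
#' allele matrices.
#'
#' @param ids individual identifiers.
#' @param loci locus names.
#' @param a1,a2 integer matrices (individuals x loci) of allele sizes in
#'   repeat units; both NA where a genotype is missing.
#' @return An object of class `msat_genotypes`.
#' @export
msat_genotypes <- function(ids, loci, a1, a2) {
  ids <- as.character(ids); loci <- as.character(loci)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (anyDuplicated(ids)) stop("duplicated individual ids")
  stopifnot(nrow(a1) == length(ids), ncol(a1) == length(loci),
            all(dim(a1) == dim(a2)))
  if (any(is.na(a1) != is.na(a2))) {
    stop("half-missing genotype: exactly two alleles or none per cell")
  }
  if (any(a1[!is.na(a1)] <= 0) || any(a2[!is.na(a2)] <= 0)) {
    stop("allele sizes must be strictly positive integers")
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, loci)
  structure(list(ids = ids, loci = loci, a1 = a1, a2 = a2),
            class = "msat_genotypes")
}

#' @export
print.msat_genotypes <- function(x, ...) {
  cat(sprintf("<msat_genotypes> %d individuals x %d loci (%.1f%% missing)\n",
              length(x$ids), length(x$loci), 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Subset genotypes by individual ids
#' @param gen a [msat_genotypes()].
#' @param ids ids to keep.
#' @export
subset_genotypes <- function(gen, ids) {
  miss <- setdiff(ids, gen$ids)
  if (length(miss)) stop("unknown ids: ", paste(miss, collapse = ", "))
  k <- match(ids, gen$ids)
  # rows come from a validated container: no revalidation needed
  structure(list(ids = as.character(ids), loci = gen$loci,
                 a1 = gen$a1[k, , drop = FALSE],
                 a2 = gen$a2[k, , drop = FALSE]),
            class = "msat_genotypes")
}

#' Read a GenePop file
#'
#' Supports 2- and 3-digit allele coding and "Pop" separators. Allele code 0
#' maps to missing. Returns genotypes plus a population map in which each
#' GenePop pop block becomes a population (named after its first individual's
#' label, the GenePop convention).
#'
#' @param path path to a GenePop file.
#' @return list with `genotypes` ([msat_genotypes()]) and `pops` (character
#'   vector of population labels, one per individual).
#' @export
read_genepop <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("parse error: truncated GenePop file")
  # line 1 is a free title; locus names follow until the first Pop
  popline <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!any(popline)) stop("parse error: no 'Pop' separator line in ", path)
  first_pop <- which(popline)[1L]
  loci <- trimws(lines[2:(first_pop - 1L)])
  # allow comma-separated locus names on a single line
  if (length(loci) == 1L && grepl(",", loci)) {
    loci <- trimws(strsplit(loci, ",")[[1]])
  }
  ids <- character(); pops <- character()
  rows1 <- list(); rows2 <- list()
  pop_idx <- 0L; pop_label <- NA_character_
  n_all_missing <- 0L
  for (i in seq(first_pop, length(lines))) {
    if (popline[i]) { pop_idx <- pop_idx + 1L; pop_label <- NA_character_; next }
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2L) stop("parse error: expected 'id , genotypes' at line ", i)
    id <- trimws(parts[1L])
    fields <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "\\s+")[[1]]
    if (length(fields) != length(loci)) {
      stop(sprintf("parse error: individual '%s' has %d genotype fields, expected %d",
                   id, length(fields), length(loci)))
    }
    if (!all(grepl("^[0-9]+$", fields))) {
      stop("parse error: non-numeric genotype field for individual '", id, "'")
    }
    w <- nchar(fields)
    if (any(w %% 2L != 0L)) {
      stop("parse error: odd-length allele field for individual '", id, "'")
    }
    half <- w %/% 2L
    if (!all(half %in% c(2L, 3L))) {
      stop("parse error: allele coding must be 2 or 3 digits (individual '", id, "')")
    }
    g1 <- as.integer(substr(fields, 1L, half))
    g2 <- as.integer(substr(fields, half + 1L, w))
    g1[g1 == 0L] <- NA_integer_; g2[g2 == 0L] <- NA_integer_
    # GenePop treats a genotype with any null allele as missing
    m <- is.na(g1) | is.na(g2)
    g1[m] <- NA_integer_; g2[m] <- NA_integer_
    if (all(m)) n_all_missing <- n_all_missing + 1L
    if (is.na(pop_label)) pop_label <- id
    ids <- c(ids, id)
    pops <- c(pops, sprintf("pop%02d_%s", pop_idx, pop_label))
    rows1[[length(rows1) + 1L]] <- g1
    rows2[[length(rows2) + 1L]] <- g2
  }
  if (n_all_missing == length(ids)) {
    warning("all genotypes missing (all-zero allele codes) in ", path)
  }
  gen <- msat_genotypes(ids, loci, do.call(rbind, rows1), do.call(rbind, rows2))
  list(genotypes = gen, pops = stats::setNames(pops, ids))
}

#' Write a GenePop file
#'
#' @param gen a [msat_genotypes()].
#' @param pops character vector (named by individual or parallel to
#'   `gen$ids`) of population labels; individuals are grouped into Pop
#'   blocks by label in order of first appearance.
#' @param path output path.
#' @param title free-text first line.
#' @param digits 2 or 3 digit allele coding.
#' @export
write_genepop <- function(gen, pops, path, title = "scenabc genepop export",
                          digits = 3L) {
  stopifnot(inherits(gen, "msat_genotypes"))
  if (!is.null(names(pops))) pops <- pops[gen$ids]
  stopifnot(length(pops) == length(gen$ids))
  fmt <- paste0("%0", digits, "d")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(title, gen$loci), con)
  for (p in unique(pops)) {
    writeLines("Pop", con)
    for (i in which(pops == p)) {
      g1 <- gen$a1[i, ]; g2 <- gen$a2[i, ]
      g1[is.na(g1)] <- 0L; g2[is.na(g2)] <- 0L
      writeLines(paste0(gen$ids[i], " , ",
                        paste(sprintf(fmt, g1), sprintf(fmt, g2),
                              sep = "", collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a population map TSV
#'
#' Three required columns: `individual`, `population`, `group` (header
#' required). Identifiers are case-sensitive exact strings.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns individual, population, group.
#' @export
read_popmap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  map <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  need <- c("individual", "population", "group")
  if (!all(need %in% names(map))) {
    stop("map file must have columns: ", paste(need, collapse = ", "))
  }
  map <- map[, need]
  validate_popmap(map)
}

#' Write a population map TSV
#' @param map data.frame with columns individual, population, group.
#' @param path output path.
#' @export
write_popmap <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_popmap <- function(map) {
  if (anyDuplicated(map$individual)) {
    stop("duplicate individual in map: ",
         paste(unique(map$individual[duplicated(map$individual)]),
               collapse = ", "))
  }
  # groups must partition populations
  pg <- unique(map[, c("population", "group")])
  if (anyDuplicated(pg$population)) {
    stop("population assigned to multiple groups: ",
         paste(unique(pg$population[duplicated(pg$population)]),
               collapse = ", "))
  }
  map
}

#' Assemble a validated multilocus dataset
#'
#' Combines an optional sequence alignment, optional microsatellite
#' genotypes and a population map into one validated container. Every
#' individual present in a marker must be mapped.
#'
#' @param alignment a [seq_alignment()] or NULL.
#' @param genotypes a [msat_genotypes()] or NULL.
#' @param map a population map data.frame or a path to a map TSV.
#' @return An object of class `multilocus_dataset`.
#' @export
assemble_dataset <- function(alignment = NULL, genotypes = NULL, map) {
  if (is.null(alignment) && is.null(genotypes)) {
    stop("at least one marker (alignment or genotypes) is required")
  }
  if (is.character(map)) map <- read_popmap(map)
  map <- validate_popmap(map)
  marker_ids <- unique(c(if (!is.null(alignment)) alignment$ids,
                         if (!is.null(genotypes)) genotypes$ids))
  unmapped <- setdiff(marker_ids, map$individual)
  if (length(unmapped)) {
    stop("individuals present in markers but absent from map: ",
         paste(unmapped, collapse = ", "))
  }
  structure(list(alignment = alignment, genotypes = genotypes, map = map),
            class = "multilocus_dataset")
}

#' @export
print.multilocus_dataset <- function(x, ...) {
  cat("<multilocus_dataset>\n")
  if (!is.null(x$alignment)) print(x$alignment) else cat("  no alignment\n")
  if (!is.null(x$genotypes)) print(x$genotypes) else cat("  no genotypes\n")
  cat(sprintf("  %d mapped individuals, %d populations, %d groups\n",
              nrow(x$map), length(unique(x$map$population)),
              length(unique(x$map$group))))
  invisible(x)
}

#' Group membership of a dataset
#' @param dataset a `multilocus_dataset`.
#' @return named integer vector: mapped individuals per group.
#' @export
group_sizes <- function(dataset) {
  tab <- table(dataset$map$group)
  stats::setNames(as.integer(tab), names(tab))
}

# ids (per marker) belonging to a group, in map order
group_ids <- function(dataset, group, marker = c("sequence", "msat")) {
  marker <- match.arg(marker)
  ids <- dataset$map$individual[dataset$map$group == group]
  pool <- switch(marker,
                 sequence = dataset$alignment$ids,
                 msat = dataset$genotypes$ids)
  ids[ids %in% pool]
}

#' Extract the alignment of one group
#' @param dataset a `multilocus_dataset`.
#' @param group group label.
#' @export
group_alignment <- function(dataset, group) {
  if (is.null(dataset$alignment)) stop("dataset has no alignment")
  ids <- group_ids(dataset, group, "sequence")
  if (!length(ids)) stop("group '", group, "' has no sequences")
  subset_alignment(dataset$alignment, ids)
}

#' Extract the genotypes of one group
#' @param dataset a `multilocus_dataset`.
#' @param group group label.
#' @export
group_genotypes <- function(dataset, group) {
  if (is.null(dataset$genotypes)) stop("dataset has no genotypes")
  ids <- group_ids(dataset, group, "msat")
  if (!length(ids)) stop("group '", group, "' has no genotypes")
  subset_genotypes(dataset$genotypes, ids)
}
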