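#' Landmark datasets
#'
#' A landmark dataset holds one 2D landmark configuration per digitization of
#' each specimen, together with the species label and the replicate number of
#' the digitization. Configurations must all have the same number of landmarks
#' `k`, and every (specimen, replicate) combination must be unique.
#'
#' @param coords numeric array `k x 2 x n` of landmark coordinates
#'   (rows are landmarks, columns are x and y, slices are configurations).
#' @param species character vector of length `n` of species labels.
#' @param specimen character vector of length `n` of specimen identifiers,
#'   unique within and across species.
#' @param replicate integer vector of length `n` of digitization replicate
#'   numbers (1-based).
#'
#' @return An object of class `landmark_dataset`: a list with elements
#'   `coords`, `species`, `specimen`, `replicate`, `k`, `n`, and a
#'   `balanced` flag that is `TRUE` when every specimen has the same number
#'   of replicates.
#' @export
landmark_dataset <- function(coords, species, specimen, replicate) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 2L)
    stop("'coords' must be a k x 2 x n array")
  k <- dim(coords)[1]
  n <- dim(coords)[3]
  if (n < 1L) stop("a dataset needs at least one configuration")
  if (k < 3L) stop("configurations need at least 3 landmarks")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  species <- as.character(species)
  specimen <- as.character(specimen)
  replicate <- as.integer(replicate)
  if (length(species) != n || length(specimen) != n || length(replicate) != n)
    stop("'species', 'specimen' and 'replicate' must have length dim(coords)[3]")
  if (any(replicate < 1L)) stop("replicate numbers must be >= 1")
  key <- paste(specimen, replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (specimen, replicate) records: ",
         paste(unique(specimen[duplicated(key)]), collapse = ", "))
  reps_per <- table(specimen)
  structure(list(
    coords = coords, species = species, specimen = specimen,
    replicate = replicate, k = k, n = n,
    n_species = length(unique(species)),
    n_specimens = length(unique(specimen)),
    balanced = length(unique(as.integer(reps_per))) == 1L
  ), class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("Landmark dataset:", x$n, "configurations of", x$k, "landmarks\n")
  cat("  ", x$n_species, "species,", x$n_specimens, "specimens,",
      if (x$balanced) sprintf("balanced (%d replicate(s)/specimen)",
                              x$n %/% x$n_specimens)
      else "unbalanced replicates", "\n")
  invisible(x)
}

## Parse a TPS ID string into species / specimen / replicate using the
## underscore convention "<species>_<individual>_<replicate>", split from the
## right so that species names may themselves contain underscores.
parse_tps_id <- function(id) {
  parts <- strsplit(id, "_", fixed = TRUE)[[1]]
  if (length(parts) < 3L)
    stop("cannot parse species/specimen/replicate from ID '", id,
         "'; expected '<species>_<individual>_<replicate>'")
  rep_tok <- parts[length(parts)]
  rep_num <- suppressWarnings(as.integer(gsub("[^0-9]", "", rep_tok)))
  if (is.na(rep_num))
    stop("non-numeric replicate token '", rep_tok, "' in ID '", id, "'")
  ind <- parts[length(parts) - 1L]
  sp <- paste(parts[seq_len(length(parts) - 2L)], collapse = "_")
  list(species = sp, specimen = paste(sp, ind, sep = "_"), replicate = rep_num)
}

#' Read a TPS landmark file
#'
#' Parses the TPS format written by landmark digitizing software: each record
#' starts with `LM=k`, followed by `k` coordinate lines, optionally followed by
#' `IMAGE=`, `ID=` and `SCALE=` lines. When `SCALE=` is present, coordinates
#' are multiplied by it. Species, specimen and replicate are recovered from the
#' `ID=` string using the convention `<species>_<individual>_<replicate>`
#' (underscore-delimited, parsed from the right), or from a sidecar manifest.
#'
#' @param path path to a TPS file.
#' @param manifest optional data frame (or path to a CSV) with columns `id`,
#'   `species`, `specimen`, `replicate`, overriding the ID-string convention.
#' @return A [landmark_dataset()].
#' @export
read_tps <- function(path, manifest = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^LM\\s*=", lines)
  if (length(starts) == 0L) stop("no 'LM=' records found in ", path)
  if (!is.null(manifest) && !is.data.frame(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  cfgs <- vector("list", length(starts))
  ids <- character(length(starts))
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:(bounds[i + 1L] - 1L)]
    k <- suppressWarnings(as.integer(sub("^LM\\s*=\\s*", "", block[1])))
    if (is.na(k) || k < 1L)
      stop("record ", i, ": malformed LM= line '", block[1], "'")
    coord_lines <- block[-1]
    is_meta <- grepl("^[A-Za-z]+\\s*=", coord_lines)
    n_coord <- if (any(is_meta)) which(is_meta)[1] - 1L else length(coord_lines)
    if (n_coord != k)
      stop("record ", i, ": LM=", k, " but ", n_coord, " coordinate line(s)")
    xy <- lapply(coord_lines[seq_len(k)], function(l) {
      v <- suppressWarnings(as.numeric(strsplit(l, "[[:space:]]+")[[1]]))
      if (length(v) != 2L || any(is.na(v)))
        stop("record ", i, ": non-numeric coordinate line '", l, "'")
      v
    })
    cfg <- do.call(rbind, xy)
    meta <- coord_lines[is_meta]
    scale_line <- grep("^SCALE\\s*=", meta, value = TRUE)
    if (length(scale_line)) {
      sc <- as.numeric(sub("^SCALE\\s*=\\s*", "", scale_line[1]))
      if (is.na(sc)) stop("record ", i, ": non-numeric SCALE value")
      cfg <- cfg * sc
    }
    id_line <- grep("^ID\\s*=", meta, value = TRUE)
    ids[i] <- if (length(id_line)) sub("^ID\\s*=\\s*", "", id_line[1])
              else sprintf("unk_%d_1", i)
    cfgs[[i]] <- cfg
  }
  ks <- vapply(cfgs, nrow, 0L)
  if (length(unique(ks)) != 1L)
    stop("mixed landmark counts in one file: ", paste(unique(ks), collapse = ", "))
  if (!is.null(manifest)) {
    m <- manifest[match(ids, manifest$id), ]
    if (anyNA(m$id)) stop("IDs missing from manifest: ",
                          paste(ids[is.na(m$id)], collapse = ", "))
    sp <- as.character(m$species); spec <- as.character(m$specimen)
    rep_num <- as.integer(m$replicate)
  } else {
    parsed <- lapply(ids, parse_tps_id)
    sp <- vapply(parsed, `[[`, "", "species")
    spec <- vapply(parsed, `[[`, "", "specimen")
    rep_num <- vapply(parsed, function(p) as.integer(p$replicate), 0L)
  }
  coords <- array(unlist(cfgs), dim = c(ks[1], 2L, length(cfgs)))
  landmark_dataset(coords, sp, spec, rep_num)
}

#' Write a landmark dataset to a TPS file
#'
#' The writer emits coordinates with 6 decimal places; `ID=` strings encode
#' species, specimen and replicate so that [read_tps()] round-trips the
#' dataset.
#'
#' @param dataset a [landmark_dataset()].
#' @param path output file path.
#' @param digits decimal places for coordinates (default 6).
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path, digits = 6) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (dataset$n < 1L) stop("cannot write an empty dataset")
  fmt <- paste0("%.", digits, "f %.", digits, "f")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(dataset$n)) {
    cfg <- dataset$coords[, , i]
    ind <- sub(paste0("^", dataset$species[i], "_"), "", dataset$specimen[i])
    writeLines(c(
      paste0("LM=", dataset$k),
      sprintf(fmt, cfg[, 1], cfg[, 2]),
      paste0("ID=", dataset$species[i], "_", ind, "_", dataset$replicate[i])
    ), con)
  }
  invisible(path)
}

#' Read a rooted Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]: accepts a file path or a
#' Newick string, and checks that the tree is rooted, that tip labels are
#' unique, and that branch lengths are present (or fills in a default) and
#' non-negative.
#'
#' @param source file path, or a Newick string (recognized by a `(` character).
#' @param default_branch_length if the tree lacks branch lengths, use this
#'   value for every edge; `NULL` (default) makes missing lengths an error.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(source, default_branch_length = NULL) {
  tr <- if (grepl("(", source[1], fixed = TRUE)) {
    tryCatch(suppressWarnings(ape::read.tree(text = source)),
             error = function(e) NULL)
  } else {
    tryCatch(suppressWarnings(ape::read.tree(source)),
             error = function(e) NULL)
  }
  if (is.null(tr)) stop("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (is.null(tr$edge.length)) {
    if (is.null(default_branch_length))
      stop("tree has no branch lengths; supply 'default_branch_length' to assume one")
    tr$edge.length <- rep(default_branch_length, nrow(tr$edge))
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (anyDuplicated(tr$tip.label)) stop("duplicated tip labels")
  ## A Newick basal polytomy cannot be distinguished from an unrooted tree;
  ## it is taken as a rooted polytomy (e.g. a star phylogeny).
  tr
}

#' Summarize a sequence alignment
#'
#' Reports the number of sequences, the alignment length, and the number of
#' variable columns. Under the default gap policy a gap is not a character
#' state: a column counts as variable iff it contains at least two distinct
#' non-gap, unambiguous residues. Flags switch gaps and IUPAC ambiguity codes
#' to being counted as distinct states.
#'
#' @param path FASTA or sequential PHYLIP alignment file.
#' @param count_gaps logical; treat `-`/`?` as a character state.
#' @param count_ambiguous logical; treat ambiguity codes (anything other than
#'   A, C, G, T, U) as distinct states.
#' @return A list of class `alignment_summary` with `n_sequences`, `length`,
#'   `n_variable`.
#' @export
summarize_alignment <- function(path, count_gaps = FALSE, count_ambiguous = FALSE) {
  first <- readLines(path, n = 1L, warn = FALSE)
  aln <- if (grepl("^\\s*>", first)) ape::read.FASTA(path)
         else ape::read.dna(path, format = "sequential")
  ch <- tryCatch(as.character(as.matrix(aln)),
                 error = function(e) stop("ragged alignment: sequences differ in length"))
  if (is.null(dim(ch))) ch <- matrix(ch, nrow = 1L)
  ch <- tolower(ch)
  gap_chars <- c("-", "?")
  base_chars <- c("a", "c", "g", "t", "u")
  n_var <- sum(apply(ch, 2, function(col) {
    states <- col
    if (!count_gaps) states <- states[!(states %in% gap_chars)]
    if (!count_ambiguous) states <- states[states %in% c(base_chars, gap_chars)]
    length(unique(states)) >= 2L
  }))
  structure(list(n_sequences = nrow(ch), length = ncol(ch), n_variable = n_var),
            class = "alignment_summary")
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat(sprintf("Alignment: %d sequences, %d columns, %d variable position(s)\n",
              x$n_sequences, x$length, x$n_variable))
  invisible(x)
}

#' Extract a landmark subset from a dataset
#'
#' Restricts every configuration to the listed landmarks, relabeled `1..m` in
#' the order given. Used to carve terminal-lobule blocks (e.g. landmarks 1-7
#' and 9-15 of a 15-landmark scheme) out of a larger configuration.
#'
#' @param dataset a [landmark_dataset()].
#' @param indices ordered vector of distinct landmark indices to keep.
#' @return A [landmark_dataset()] with `length(indices)` landmarks.
#' @export
extract_landmarks <- function(dataset, indices) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("duplicate landmark indices")
  if (any(indices < 1L | indices > dataset$k))
    stop("landmark index out of range 1..", dataset$k)
  landmark_dataset(dataset$coords[indices, , , drop = FALSE],
                   dataset$species, dataset$specimen, dataset$replicate)
}
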