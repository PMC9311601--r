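#' Landmark dataset container
#'
#' Bundles digitized 2D landmark configurations with specimen metadata. Each
#' record is one digitization (one specimen x replicate); all records must
#' share the same number of landmarks K and contain only finite coordinates.
#'
#' @param coords numeric array `n x K x 2` (records x landmarks x (x, y)), or a
#'   list of `K x 2` matrices.
#' @param specimen_id character vector of length n.
#' @param sex factor or character vector with levels `"F"`/`"M"` (may contain
#'   `NA` when sex is unknown).
#' @param replicate integer vector (>= 1) giving the digitization replicate.
#' @param scale optional numeric vector of digitizing scale factors
#'   (units per coordinate); `NA` where absent.
#' @return An object of class `landmark_dataset`: a list with elements
#'   `coords`, `specimen_id`, `sex`, `replicate`, `scale`, `K`, `n`.
#' @export
landmark_dataset <- function(coords, specimen_id, sex = NULL, replicate = NULL,
                             scale = NULL) {
  if (is.list(coords)) {
    if (length(coords) == 0L) {
      coords <- array(numeric(0), dim = c(0L, 0L, 2L))
    } else {
      K <- nrow(coords[[1L]])
      if (any(vapply(coords, nrow, 0L) != K))
        stop("structure error: configurations have differing landmark counts")
      coords <- aperm(simplify2array(coords), c(3L, 1L, 2L))
    }
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3L] == 2L)
  n <- dim(coords)[1L]
  if (length(specimen_id) != n)
    stop("structure error: specimen_id length does not match record count")
  if (is.null(sex)) sex <- rep(NA_character_, n)
  if (is.null(replicate)) replicate <- rep(1L, n)
  if (is.null(scale)) scale <- rep(NA_real_, n)
  sex <- factor(as.character(sex), levels = c("F", "M"))
  replicate <- as.integer(replicate)
  if (n > 0L && !all(is.finite(coords)))
    stop("structure error: non-finite coordinates in dataset")
  if (n > 0L && any(replicate < 1L, na.rm = TRUE))
    stop("structure error: replicate indices must be >= 1")
  reps <- table(specimen_id)
  if (length(unique(reps)) > 1L)
    stop("structure error: specimens differ in number of replicates (",
         paste(range(reps), collapse = "-"), ")")
  structure(list(coords = coords, specimen_id = as.character(specimen_id),
                 sex = sex, replicate = replicate, scale = as.numeric(scale),
                 K = dim(coords)[2L], n = n),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("landmark_dataset:", length(unique(x$specimen_id)), "specimens,",
      x$n, "records,", x$K, "landmarks (2D)\n")
  if (any(!is.na(x$sex)))
    print(table(sex = x$sex[!duplicated(x$specimen_id)]))
  invisible(x)
}

#' Pairing scheme for object symmetry
#'
#' Describes which landmarks form bilateral left/right pairs and which lie on
#' the midline (axis of bilateral symmetry). All indices are 1-based.
#'
#' @param pairs integer matrix with columns `left`, `right` (one row per pair).
#' @param midline integer vector of unpaired, on-axis landmark indices.
#' @param axis_reference index of the midline landmark anchoring the
#'   triangle-area asymmetry descriptor (the anteriormost midline point).
#' @param longitudinal_order permutation of `1:nrow(pairs)` ordering the pairs
#'   from anterior to posterior; defaults to file order.
#' @return Object of class `pairing_scheme` with elements `pairs`, `midline`,
#'   `axis_reference`, `longitudinal_order`, `K`, `pair_labels`.
#' @export
pairing_scheme <- function(pairs, midline, axis_reference,
                           longitudinal_order = seq_len(nrow(pairs))) {
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("left", "right")))
  midline <- as.integer(midline)
  axis_reference <- as.integer(axis_reference)
  K <- 2L * nrow(pairs) + length(midline)
  idx <- c(pairs, midline)
  if (anyDuplicated(idx))
    stop("config error: landmark assigned to more than one pair/midline slot")
  if (!setequal(idx, seq_len(K)))
    stop("config error: pairs and midline must cover 1..K exactly; indices ",
         "out of range or missing")
  if (!(axis_reference %in% midline))
    stop("config error: axis_reference must be a midline landmark")
  if (!setequal(longitudinal_order, seq_len(nrow(pairs))))
    stop("config error: longitudinal_order must permute the pair indices")
  structure(list(pairs = pairs, midline = midline,
                 axis_reference = axis_reference,
                 longitudinal_order = as.integer(longitudinal_order), K = K,
                 pair_labels = sprintf("%02d-%02d", pairs[, 1L], pairs[, 2L])),
            class = "pairing_scheme")
}

#' @export
print.pairing_scheme <- function(x, ...) {
  cat("pairing_scheme: K =", x$K, "|", nrow(x$pairs), "pairs,",
      length(x$midline), "midline landmarks (axis ref:", x$axis_reference, ")\n")
  invisible(x)
}

#' Module partition of a landmark configuration
#'
#' @param name partition label (e.g. `"developmental"`).
#' @param assignment vector of length K giving each landmark's module label
#'   (character or factor); element i is the module of landmark i.
#' @param allow_singleton allow modules with < 2 landmarks (used internally by
#'   permutation machinery; fixture partitions must not need it).
#' @return Object of class `module_partition` with `name`, `assignment`
#'   (character), `modules` (unique labels), `module_count`.
#' @export
module_partition <- function(name, assignment, allow_singleton = FALSE) {
  assignment <- as.character(assignment)
  if (anyNA(assignment))
    stop("config error: every landmark must be assigned to a module")
  tab <- table(assignment)
  if (!allow_singleton && any(tab < 2L))
    stop("config error: module(s) with fewer than 2 landmarks: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  structure(list(name = as.character(name), assignment = assignment,
                 modules = sort(unique(assignment)),
                 module_count = length(tab)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module_partition '", x$name, "': ", x$module_count, " module(s) over ",
      length(x$assignment), " landmarks\n", sep = "")
  invisible(x)
}

## ---- TPS input/output -------------------------------------------------------

## Dialect: LM=, coordinate lines, ID=, IMAGE=, SCALE=; CURVES=/POINTS=
## sections are skipped with one warning. IDs of the form "<specimen>_<k>"
## carry the replicate number; otherwise replicate defaults to 1.

#' Read a TPS landmark file
#'
#' Parses the tpsDig2 dialect of the TPS format: one block per digitized
#' specimen starting with `LM=<count>`, followed by that many `x y` coordinate
#' lines and optional `ID=`, `IMAGE=`, `SCALE=` keys. `CURVES=`/`POINTS=`
#' sections are ignored with a warning. Specimen IDs ending in `_<integer>`
#' are split into specimen_id and replicate; sex is joined from an optional
#' sidecar metadata table (see [read_specimen_metadata()]).
#'
#' @param path TPS file path.
#' @param metadata optional data.frame with columns `specimen_id` and `sex`
#'   (and optionally `replicate`), as returned by [read_specimen_metadata()].
#' @return A [landmark_dataset()].
#' @export
read_tps <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  configs <- list(); ids <- character(); scales <- numeric()
  i <- 1L; block <- 0L; warned_curves <- FALSE
  while (i <= length(lines)) {
    ln <- lines[i]
    if (ln == "") { i <- i + 1L; next }
    if (!grepl("^LM=", ln, ignore.case = TRUE))
      stop("parse error: expected LM= at line ", i, ", got: ", ln)
    block <- block + 1L
    k <- suppressWarnings(as.integer(sub("^LM=", "", ln, ignore.case = TRUE)))
    if (is.na(k) || k < 0L)
      stop("parse error: malformed LM count in block ", block)
    i <- i + 1L
    coords <- matrix(NA_real_, k, 2L)
    for (j in seq_len(k)) {
      if (i > length(lines))
        stop("parse error: block ", block, ": LM=", k,
             " but file ends after ", j - 1L, " coordinate lines")
      fields <- strsplit(lines[i], "[ \t]+")[[1L]]
      vals <- suppressWarnings(as.numeric(fields))
      if (length(vals) == 3L && all(is.finite(vals)))
        stop("structure error: block ", block,
             ": 3 coordinate columns found; only 2D configurations supported")
      if (length(vals) != 2L || anyNA(vals))
        stop("parse error: block ", block, ", landmark ", j,
             ": malformed coordinate line: ", lines[i])
      coords[j, ] <- vals
      i <- i + 1L
    }
    id <- NA_character_; sc <- NA_real_
    while (i <= length(lines) && !grepl("^LM=", lines[i], ignore.case = TRUE)) {
      ln <- lines[i]
      if (grepl("^(CURVES|POINTS)=", ln, ignore.case = TRUE)) {
        if (!warned_curves) {
          warning("TPS CURVES/POINTS sections ignored (not used by the analysis)")
          warned_curves <- TRUE
        }
      } else if (grepl("^ID=", ln, ignore.case = TRUE)) {
        id <- sub("^ID=", "", ln, ignore.case = TRUE)
      } else if (grepl("^IMAGE=", ln, ignore.case = TRUE)) {
        if (is.na(id)) id <- sub("^IMAGE=", "", ln, ignore.case = TRUE)
      } else if (grepl("^SCALE=", ln, ignore.case = TRUE)) {
        sc <- suppressWarnings(as.numeric(sub("^SCALE=", "", ln,
                                              ignore.case = TRUE)))
        if (is.na(sc) || sc <= 0)
          stop("parse error: block ", block, ": invalid SCALE value")
      } else if (ln != "") {
        stop("parse error: block ", block, ": unexpected line: ", ln)
      }
      i <- i + 1L
    }
    if (is.na(id)) id <- sprintf("specimen_%03d", block)
    configs[[block]] <- coords; ids[block] <- id; scales[block] <- sc
  }
  if (block == 0L)
    return(landmark_dataset(array(numeric(0), c(0L, 0L, 2L)),
                            character(0)))
  ks <- vapply(configs, nrow, 0L)
  if (length(unique(ks)) > 1L)
    stop("structure error: inconsistent landmark counts across blocks: ",
         paste(unique(ks), collapse = ", "))
  ## "<specimen>_<k>" naming convention carries the replicate
  has_rep <- grepl("_[0-9]+$", ids)
  replicate <- ifelse(has_rep, as.integer(sub("^.*_", "", ids)), 1L)
  specimen <- ifelse(has_rep, sub("_[0-9]+$", "", ids), ids)
  sex <- rep(NA_character_, block)
  if (!is.null(metadata)) {
    m <- match(specimen, metadata$specimen_id)
    if (anyNA(m))
      stop("structure error: specimens missing from metadata: ",
           paste(unique(specimen[is.na(m)]), collapse = ", "))
    sex <- as.character(metadata$sex[m])
  }
  landmark_dataset(configs, specimen, sex = sex, replicate = replicate,
                   scale = scales)
}

#' Write a landmark dataset as a TPS file
#'
#' Emits one canonical block per record: `LM=`, coordinate lines (`%.6f`),
#' `ID=<specimen_id>_<replicate>` and `SCALE=` when present. Writing then
#' re-reading reproduces coordinates to 6 decimals and is byte-stable.
#'
#' @param dataset a [landmark_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(dataset, path) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("I/O error: cannot open for writing: ", path))
  on.exit(close(con))
  for (i in seq_len(dataset$n)) {
    cat(sprintf("LM=%d\n", dataset$K), file = con)
    xy <- dataset$coords[i, , , drop = TRUE]
    cat(sprintf("%.6f %.6f\n", xy[, 1L], xy[, 2L]), sep = "", file = con)
    cat(sprintf("ID=%s_%d\n", dataset$specimen_id[i], dataset$replicate[i]),
        file = con)
    if (!is.na(dataset$scale[i]))
      cat(sprintf("SCALE=%.6f\n", dataset$scale[i]), file = con)
  }
  invisible(path)
}

#' Read a sidecar specimen metadata table
#'
#' CSV with columns `specimen_id`, `sex` (`F`/`M`) and optionally `replicate`.
#' TPS has no standard field for sex or replicate, hence the sidecar.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_specimen_metadata <- function(path) {
  if (!file.exists(path)) stop("I/O error: file not found: ", path)
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "sex")
  if (!all(need %in% names(md)))
    stop("structure error: metadata must have columns specimen_id, sex")
  bad <- !md$sex %in% c("F", "M")
  if (any(bad))
    stop("structure error: sex must be F or M; offending rows: ",
         paste(which(bad), collapse = ", "))
  md
}

#' Write the sidecar metadata for a dataset
#' @param dataset a [landmark_dataset()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_specimen_metadata <- function(dataset, path) {
  keep <- !duplicated(dataset$specimen_id)
  utils::write.csv(data.frame(specimen_id = dataset$specimen_id[keep],
                              sex = as.character(dataset$sex[keep])),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- analysis configuration -------------------------------------------------

#' Load a pairing-scheme + partitions configuration
#'
#' YAML schema (all landmark indices 1-based):
#' \preformatted{
#' landmarks: 33
#' pairs:            # [left, right], anterior-to-posterior order
#'   - [28, 2]
#'   - ...
#' midline: [1, 15, 33]
#' axis_reference: 1
#' longitudinal_order: [1, 2, ...]   # optional; defaults to pair file order
#' partitions:
#'   - name: developmental
#'     modules:
#'       cephalic: [1, 2, ...]
#'       thoracic: [...]
#' }
#'
#' @param path YAML config path. Defaults to the shipped cephalothorax
#'   configuration (a reconstruction of the 33-landmark map: 15 bilateral
#'   pairs, 3 midline landmarks, 7 modularity hypotheses).
#' @return list with elements `scheme` ([pairing_scheme()]) and `partitions`
#'   (named list of [module_partition()]).
#' @export
load_analysis_config <- function(path = system.file("extdata",
                                                    "cephalothorax_config.yaml",
                                                    package = "symmod")) {
  if (!nzchar(path) || !file.exists(path))
    stop("I/O error: config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (f in c("landmarks", "pairs", "midline", "axis_reference", "partitions"))
    if (is.null(cfg[[f]])) stop("config error: missing field '", f, "'")
  K <- as.integer(cfg$landmarks)
  pairs <- do.call(rbind, lapply(cfg$pairs, function(p) {
    if (length(p) != 2L) stop("config error: each pair must be [left, right]")
    as.integer(p)
  }))
  lord <- if (is.null(cfg$longitudinal_order)) seq_len(nrow(pairs))
          else as.integer(cfg$longitudinal_order)
  scheme <- pairing_scheme(pairs, cfg$midline, cfg$axis_reference, lord)
  if (scheme$K != K)
    stop("config error: landmarks=", K, " but pairs/midline imply K=",
         scheme$K)
  partitions <- lapply(cfg$partitions, function(p) {
    if (is.null(p$name) || is.null(p$modules))
      stop("config error: each partition needs 'name' and 'modules'")
    assign <- rep(NA_character_, K)
    for (mod in names(p$modules)) {
      idx <- as.integer(p$modules[[mod]])
      if (any(idx < 1L | idx > K))
        stop("config error: partition '", p$name,
             "': landmark index out of range in module '", mod, "'")
      if (any(!is.na(assign[idx])))
        stop("config error: partition '", p$name,
             "': landmark assigned to two modules")
      assign[idx] <- mod
    }
    if (anyNA(assign))
      stop("config error: partition '", p$name, "': unassigned landmarks: ",
           paste(which(is.na(assign)), collapse = ", "))
    module_partition(p$name, assign)
  })
  names(partitions) <- vapply(partitions, `[[`, "", "name")
  list(scheme = scheme, partitions = partitions)
}
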