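#' Parse a PDBbind-style affinity index file
#'
#' Whitespace-delimited text, comment lines starting with '#'. Each data
#' line holds at least four fields: complex code, resolution, year and the
#' -log10(Kd/Ki) affinity label (further fields ignored).
#'
#' @param path Index file path.
#' @param tier Quality tier tag attached to every record
#'   (\code{"refined"} or \code{"general-only"}).
#' @return Data frame of complex records: \code{id}, \code{label},
#'   \code{tier}.
#' @export
parse_index <- function(path, tier = c("refined", "general-only")) {
  tier <- match.arg(tier)
  if (!file.exists(path)) stop("index file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) stop("index file has no data lines: ", path)
  ids <- character(length(keep))
  labels <- numeric(length(keep))
  for (k in seq_along(keep)) {
    f <- strsplit(trimws(lines[keep[k]]), "\\s+")[[1]]
    if (length(f) < 4 || is.na(suppressWarnings(as.numeric(f[4]))))
      stop("malformed index line ", keep[k], " in ", path, ": ",
           lines[keep[k]])
    ids[k] <- f[1]
    labels[k] <- as.numeric(f[4])
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate complex code(s) in index: ", paste(dup, collapse = ", "))
  data.frame(id = ids, label = labels, tier = tier, stringsAsFactors = FALSE)
}

#' Split complexes into train / validation / test sets
#'
#' Removes the named test-set complexes from the pool, draws the validation
#' set uniformly at random (seeded) as \code{val_fraction} of the remaining
#' pool -- optionally restricted to refined-tier records -- and assigns the
#' remainder to training. All sets are disjoint by complex id.
#'
#' @param records Data frame of complex records (\code{id}, \code{label},
#'   \code{tier}, plus any extra columns carried along).
#' @param exclude_test_ids Named list of character vectors of complex ids to
#'   hold out as test sets (e.g. core-set id lists). Ids not present in
#'   \code{records} are warned about and ignored.
#' @param val_fraction Fraction of the post-exclusion pool used for
#'   validation (default 0.1, the 9:1 split).
#' @param val_pool \code{"any"} or \code{"refined"}: tier the validation
#'   set may be drawn from.
#' @param seed Integer seed for the validation draw.
#' @return A \code{split_manifest}: list with \code{train},
#'   \code{validation} (data frames), \code{test} (named list of data
#'   frames), \code{train_poses}, \code{val_poses} (pose tables, empty until
#'   \code{\link{augment_with_poses}}), \code{seed}.
#' @export
make_splits <- function(records, exclude_test_ids = list(),
                        val_fraction = 0.1, val_pool = c("any", "refined"),
                        seed = 1L) {
  val_pool <- match.arg(val_pool)
  stopifnot(is.data.frame(records), !anyDuplicated(records$id),
            val_fraction >= 0, val_fraction < 1)
  test <- list()
  pool <- records
  for (nm in names(exclude_test_ids)) {
    ids <- exclude_test_ids[[nm]]
    missing <- setdiff(ids, records$id)
    if (length(missing))
      warning(length(missing), " excluded id(s) for test set '", nm,
              "' not present in the index")
    test[[nm]] <- records[records$id %in% ids, , drop = FALSE]
    pool <- pool[!pool$id %in% ids, , drop = FALSE]
  }
  if (nrow(pool) == 0) stop("no complexes left after test-set exclusion")
  n_val <- round(val_fraction * nrow(pool))
  eligible <- if (val_pool == "refined")
    which(pool$tier == "refined") else seq_len(nrow(pool))
  if (n_val > length(eligible))
    stop("validation pool (", length(eligible),
         " eligible) smaller than requested validation size (", n_val, ")")
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  val_idx <- sort(sample(eligible, n_val))
  manifest <- list(train = pool[setdiff(seq_len(nrow(pool)), val_idx), ,
                                drop = FALSE],
                   validation = pool[val_idx, , drop = FALSE],
                   test = test,
                   train_poses = empty_pose_table(),
                   val_poses = empty_pose_table(),
                   seed = as.integer(seed))
  rownames(manifest$train) <- rownames(manifest$validation) <- NULL
  structure(manifest, class = "split_manifest")
}

empty_pose_table <- function() {
  data.frame(parent_id = character(0), pose_path = character(0),
             docking_score = numeric(0), rmsd = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.split_manifest <- function(x, ...) {
  cat("Dataset split (seed ", x$seed, "): ", nrow(x$train), " train / ",
      nrow(x$validation), " validation", sep = "")
  for (nm in names(x$test)) cat(" / ", nrow(x$test[[nm]]), " test[", nm, "]",
                                sep = "")
  cat("\n")
  np <- nrow(x$train_poses) + nrow(x$val_poses)
  if (np > 0) cat("  + ", nrow(x$train_poses), " train / ",
                  nrow(x$val_poses), " validation docking poses\n", sep = "")
  invisible(x)
}

#' Attach filtered docking poses to a split
#'
#' Per complex: poses with RMSD above \code{rmsd_max} (vs the crystal pose)
#' are discarded, and among the survivors at most \code{max_poses} with the
#' best (lowest, i.e. most favorable energy) docking score are kept. Poses
#' are attached to the parent complex's own split; test complexes never
#' gain poses -- a pose referencing a test id is rejected with a warning.
#' Augmentation never changes any split's complex-id membership.
#'
#' @param manifest A \code{split_manifest}.
#' @param poses Data frame with columns \code{parent_id}, \code{pose_path},
#'   \code{docking_score}, \code{rmsd}.
#' @param rmsd_max RMSD cutoff in Angstrom (default 3.0).
#' @param max_poses Per-complex cap on retained poses (default 3).
#' @return The manifest with \code{train_poses} / \code{val_poses} filled.
#' @export
augment_with_poses <- function(manifest, poses, rmsd_max = 3.0,
                               max_poses = 3L) {
  stopifnot(inherits(manifest, "split_manifest"),
            all(c("parent_id", "pose_path", "docking_score", "rmsd") %in%
                  names(poses)))
  if (any(poses$rmsd < 0)) stop("negative pose RMSD")
  test_ids <- unlist(lapply(manifest$test, function(d) d$id),
                     use.names = FALSE)
  in_test <- poses$parent_id %in% test_ids
  if (any(in_test)) {
    warning(sum(in_test), " pose(s) referencing test complexes rejected")
    poses <- poses[!in_test, , drop = FALSE]
  }
  known <- c(manifest$train$id, manifest$validation$id)
  unknown <- !(poses$parent_id %in% known)
  if (any(unknown)) {
    warning(sum(unknown), " pose(s) referencing unknown complexes rejected")
    poses <- poses[!unknown, , drop = FALSE]
  }
  poses <- poses[poses$rmsd <= rmsd_max, , drop = FALSE]
  kept <- do.call(rbind, lapply(split(poses, poses$parent_id), function(p) {
    p[order(p$docking_score)[seq_len(min(nrow(p), max_poses))], ,
      drop = FALSE]
  }))
  if (is.null(kept)) kept <- empty_pose_table()
  rownames(kept) <- NULL
  manifest$train_poses <- kept[kept$parent_id %in% manifest$train$id, ,
                               drop = FALSE]
  manifest$val_poses <- kept[kept$parent_id %in% manifest$validation$id, ,
                             drop = FALSE]
  rownames(manifest$train_poses) <- rownames(manifest$val_poses) <- NULL
  manifest
}

#' Write a split manifest to JSON
#'
#' @param manifest A \code{split_manifest}.
#' @param path Output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}
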