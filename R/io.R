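#' Construct a SAXS curve
#'
#' A SAXS curve holds the measured scattering-vector grid `q` (1/Angstrom),
#' the measured intensities and their one-sigma counting errors. It is a
#' tibble with columns `q`, `intensity`, `error`, so all dplyr/ggplot2 verbs
#' apply directly.
#'
#' @param q Numeric vector of scattering-vector magnitudes (1/Angstrom),
#'   strictly increasing.
#' @param intensity Measured intensities (arbitrary units).
#' @param error One-sigma experimental errors, same units as `intensity`;
#'   all strictly positive.
#' @return A tibble of class `saxs_curve`.
#' @examples
#' saxs_curve(q = c(0.01, 0.02), intensity = c(100, 90), error = c(1, 1.1))
#' @export
saxs_curve <- function(q, intensity, error) {
  out <- tibble(q = as.numeric(q),
                intensity = as.numeric(intensity),
                error = as.numeric(error))
  class(out) <- c("saxs_curve", class(out))
  validate_saxs_curve(out)
}

validate_saxs_curve <- function(x) {
  if (nrow(x) < 2L) abort("a SAXS curve needs at least 2 points")
  if (anyNA(x$q) || anyNA(x$intensity) || anyNA(x$error))
    abort("SAXS curve contains missing values")
  bad <- which(x$error <= 0)
  if (length(bad) > 0L)
    abort(paste0("non-positive error at row(s): ",
                 paste(bad, collapse = ", ")))
  if (any(diff(x$q) <= 0))
    abort("q must be strictly increasing")
  x
}

#' Read a 3-column SAXS data file
#'
#' Reads the conventional ATSAS-style `.dat` layout: whitespace-separated
#' columns `q`, intensity, error. Leading non-numeric header lines (sample
#' descriptions, column captions) are skipped; the first line whose first
#' three fields all parse as numbers starts the data block.
#'
#' @param path Path to the text file.
#' @return A [saxs_curve()].
#' @export
read_saxs_curve <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  rows <- vector("list", length(lines))
  in_data <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) {
      if (in_data) break else next
    }
    fields <- strsplit(ln, "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (length(fields) < 3L || anyNA(vals)) {
      if (in_data)
        abort(paste0("malformed data row at line ", i, ": '", ln, "'"))
      next  # still in the header
    }
    in_data <- TRUE
    rows[[i]] <- vals
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 2L)
    abort(paste0("fewer than 2 parseable data rows in ", path))
  dat <- do.call(rbind, rows)
  bad <- which(dat[, 3] <= 0)
  if (length(bad) > 0L)
    abort(paste0("non-positive error in data row(s): ",
                 paste(bad, collapse = ", ")))
  saxs_curve(dat[, 1], dat[, 2], dat[, 3])
}

#' Write a SAXS curve to a 3-column text file
#'
#' Values are written with enough digits for a lossless round-trip through
#' [read_saxs_curve()] at 6 significant figures and beyond.
#'
#' @param curve A [saxs_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saxs_curve <- function(curve, path) {
  validate_saxs_curve(curve)
  lines <- sprintf("%.10g %.10g %.10g", curve$q, curve$intensity, curve$error)
  writeLines(c("# q intensity error", lines), path)
  invisible(path)
}

#' Construct a structural library
#'
#' A structural library is the pool of candidate conformers, each carrying
#' precomputed observables: a scattering profile evaluated on the
#' experimental q-grid, optionally predicted chemical shifts with their
#' prediction uncertainties, and optionally a scalar structural energy
#' (lower = more favorable).
#'
#' @param ids Character vector of conformer identifiers.
#' @param q The q-grid the profiles are evaluated on.
#' @param profiles Matrix, one row per conformer, one column per q-point;
#'   all intensities strictly positive.
#' @param cs_pred Optional matrix of predicted chemical shifts (ppm), one
#'   row per conformer, one column per shift.
#' @param cs_pred_err Optional per-shift prediction uncertainty (ppm);
#'   scalar or vector of length `ncol(cs_pred)`.
#' @param cs_labels Optional residue/atom labels for the shift columns.
#' @param energies Optional numeric vector of per-conformer energies.
#' @return An object of class `structural_library`.
#' @export
structural_library <- function(ids, q, profiles, cs_pred = NULL,
                               cs_pred_err = NULL, cs_labels = NULL,
                               energies = NULL) {
  ids <- as.character(ids)
  profiles <- as.matrix(profiles)
  if (nrow(profiles) != length(ids))
    abort("profiles must have one row per conformer id")
  if (ncol(profiles) != length(q))
    abort("profiles column count must match the q-grid length")
  if (any(profiles <= 0))
    abort("all profile intensities must be positive")
  if (!is.null(cs_pred)) {
    cs_pred <- as.matrix(cs_pred)
    if (nrow(cs_pred) != length(ids))
      abort("cs_pred must have one row per conformer")
    if (!is.null(cs_labels) && length(cs_labels) != ncol(cs_pred))
      abort("cs_labels length must match cs_pred columns")
    if (!is.null(cs_pred_err)) {
      if (length(cs_pred_err) == 1L)
        cs_pred_err <- rep(as.numeric(cs_pred_err), ncol(cs_pred))
      if (length(cs_pred_err) != ncol(cs_pred))
        abort("cs_pred_err must be scalar or one value per shift")
      if (any(cs_pred_err < 0)) abort("cs_pred_err must be non-negative")
    }
  }
  if (!is.null(energies)) {
    energies <- as.numeric(energies)
    if (length(energies) != length(ids))
      abort(paste0("energy count (", length(energies),
                   ") does not match library size (", length(ids), ")"))
    names(energies) <- ids
  }
  rownames(profiles) <- ids
  structure(list(ids = ids, q = as.numeric(q), profiles = profiles,
                 cs_pred = cs_pred, cs_pred_err = cs_pred_err,
                 cs_labels = cs_labels, energies = energies),
            class = "structural_library")
}

#' @export
print.structural_library <- function(x, ...) {
  cat("<structural_library> ", length(x$ids), " conformers, ",
      length(x$q), " q-points", sep = "")
  if (!is.null(x$cs_pred)) cat(", ", ncol(x$cs_pred), " chemical shifts", sep = "")
  if (!is.null(x$energies)) cat(", energies", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.structural_library <- function(x) length(x$ids)

#' Subset a structural library by conformer
#'
#' @param library A [structural_library()].
#' @param members Conformer ids (character) or indices.
#' @return A `structural_library` restricted to `members`, in that order.
#' @export
subset_library <- function(library, members) {
  idx <- if (is.character(members)) match(members, library$ids) else as.integer(members)
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(library$ids)))
    abort("unknown conformer in subset")
  structural_library(
    ids = library$ids[idx], q = library$q,
    profiles = library$profiles[idx, , drop = FALSE],
    cs_pred = if (!is.null(library$cs_pred)) library$cs_pred[idx, , drop = FALSE],
    cs_pred_err = library$cs_pred_err, cs_labels = library$cs_labels,
    energies = if (!is.null(library$energies)) unname(library$energies[idx]))
}

#' Read a per-conformer scattering-profile matrix
#'
#' Layout: first column q, subsequent columns one conformer each; an
#' optional leading `#` header line names the conformers. The q-grid must
#' match the experimental curve to within 1e-6 relative.
#'
#' @param path Path to the whitespace/TSV matrix file.
#' @param curve The experimental [saxs_curve()] the profiles are paired with.
#' @return A [structural_library()].
#' @export
read_profile_matrix <- function(path, curve) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  ids <- NULL
  if (startsWith(trimws(lines[[1]]), "#")) {
    hdr <- strsplit(trimws(sub("^#", "", lines[[1]])), "[[:space:]]+")[[1]]
    # drop a leading 'q' caption if present
    if (length(hdr) >= 1L && tolower(hdr[[1]]) == "q") hdr <- hdr[-1]
    ids <- hdr
    lines <- lines[-1]
  }
  dat <- do.call(rbind, lapply(seq_along(lines), function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[[i]]),
                                                 "[[:space:]]+")[[1]]))
    if (anyNA(vals)) abort(paste0("malformed profile row at line ", i))
    vals
  }))
  qf <- dat[, 1]
  if (length(qf) != nrow(curve))
    abort(paste0("profile grid has ", length(qf), " points; curve has ",
                 nrow(curve)))
  rel <- abs(qf - curve$q) / pmax(abs(curve$q), 1e-12)
  off <- which(rel > 1e-6)
  if (length(off) > 0L)
    abort(paste0("q-grid mismatch with curve, first offending index: ",
                 off[[1]], " (profile q=", qf[off[[1]]], ", curve q=",
                 curve$q[off[[1]]], ")"))
  profiles <- t(dat[, -1, drop = FALSE])
  if (is.null(ids) || length(ids) != nrow(profiles))
    ids <- sprintf("conf_%03d", seq_len(nrow(profiles)))
  structural_library(ids = ids, q = curve$q, profiles = profiles)
}

#' Write a profile matrix
#'
#' Inverse of [read_profile_matrix()]: first column q, one column per
#' conformer, `#` header with conformer ids.
#'
#' @param library A [structural_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(library, path) {
  hdr <- paste("# q", paste(library$ids, collapse = " "))
  body <- vapply(seq_along(library$q), function(j) {
    paste(sprintf("%.10g", c(library$q[[j]], library$profiles[, j])),
          collapse = " ")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a per-conformer energy list
#'
#' One numeric energy per line (or whitespace-separated on one line);
#' `#` comment lines ignored. The count must match the library size.
#'
#' @param path Path to the energy file.
#' @param library Optional [structural_library()] to check the count against.
#' @return Numeric vector of energies.
#' @export
read_energies <- function(path, library = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != "" & !startsWith(trimws(lines), "#")]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines),
                                                      "[[:space:]]+"))))
  if (anyNA(vals)) abort("non-numeric value in energy file")
  if (!is.null(library) && length(vals) != length(library$ids))
    abort(paste0("energy count (", length(vals),
                 ") does not match library size (", length(library$ids), ")"))
  vals
}

#' Construct experimental chemical-shift data
#'
#' A tibble with columns `label` (residue/atom identifier used to align
#' with predictions), `shift` (ppm) and `error` (experimental error, ppm;
#' a scalar is broadcast).
#'
#' @param labels Character identifiers.
#' @param shifts Experimental shifts (ppm).
#' @param errors Experimental errors (ppm, non-negative); scalar or
#'   per-measurement.
#' @return A tibble of class `chemical_shift_data`.
#' @export
chemical_shift_data <- function(labels, shifts, errors) {
  if (length(errors) == 1L) errors <- rep(errors, length(shifts))
  if (length(labels) != length(shifts) || length(shifts) != length(errors))
    abort("labels, shifts and errors must have equal lengths")
  if (any(errors < 0)) abort("experimental CS errors must be non-negative")
  out <- tibble(label = as.character(labels), shift = as.numeric(shifts),
                error = as.numeric(errors))
  class(out) <- c("chemical_shift_data", class(out))
  out
}

#' Read an experimental chemical-shift table
#'
#' TSV/whitespace table with columns label, shift, error (a missing third
#' column yields zero experimental error, leaving only the prediction
#' uncertainty in the combined variance).
#'
#' @param path Path to the table.
#' @return A [chemical_shift_data()] tibble.
#' @export
read_cs_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  dat <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(dat) < 2L) abort("chemical-shift table needs at least 2 columns")
  err <- if (ncol(dat) >= 3L) as.numeric(dat[[3]]) else 0
  chemical_shift_data(dat[[1]], as.numeric(dat[[2]]), err)
}

#' Read per-conformer chemical-shift predictions
#'
#' Layout mirrors the profile matrix: a `#` header with `label` plus
#' conformer ids, then one row per shift: label followed by one predicted
#' value per conformer. Prediction uncertainties go in a separate
#' two-column file (label, error) read with `err_path`.
#'
#' @param path Predictions table.
#' @param err_path Optional per-shift prediction-uncertainty table.
#' @return List with `labels`, `cs_pred` (conformers x shifts matrix) and
#'   `cs_pred_err` (vector or NULL).
#' @export
read_cs_predictions <- function(path, err_path = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  ids <- NULL
  if (startsWith(trimws(lines[[1]]), "#")) {
    hdr <- strsplit(trimws(sub("^#", "", lines[[1]])), "[[:space:]]+")[[1]]
    if (length(hdr) >= 1L && tolower(hdr[[1]]) %in% c("label", "id")) hdr <- hdr[-1]
    ids <- hdr
    lines <- lines[-1]
  }
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  labels <- vapply(parts, `[[`, character(1), 1L)
  vals <- lapply(parts, function(p) suppressWarnings(as.numeric(p[-1])))
  if (length(unique(lengths(vals))) != 1L || anyNA(unlist(vals)))
    abort("ragged or non-numeric chemical-shift prediction table")
  cs_pred <- t(do.call(rbind, vals))  # conformers x shifts
  colnames(cs_pred) <- labels
  if (!is.null(ids) && length(ids) == nrow(cs_pred)) rownames(cs_pred) <- ids
  cs_pred_err <- NULL
  if (!is.null(err_path)) {
    et <- utils::read.table(err_path, header = FALSE, comment.char = "#",
                            stringsAsFactors = FALSE)
    cs_pred_err <- setNames(as.numeric(et[[2]]), as.character(et[[1]]))[labels]
    if (anyNA(cs_pred_err))
      abort("prediction-uncertainty table missing labels present in predictions")
    cs_pred_err <- unname(cs_pred_err)
  }
  list(labels = labels, cs_pred = cs_pred, cs_pred_err = cs_pred_err)
}

#' Align predicted and experimental chemical shifts by label
#'
#' Takes the intersection of the experimental and predicted label sets;
#' labels present on only one side are dropped with a warning reporting
#' the mismatch count.
#'
#' @param cs_data Experimental [chemical_shift_data()].
#' @param predictions List as returned by [read_cs_predictions()] (fields
#'   `labels`, `cs_pred`, `cs_pred_err`).
#' @return List with aligned `cs_data`, `cs_pred`, `cs_pred_err`.
#' @export
align_cs <- function(cs_data, predictions) {
  common <- intersect(cs_data$label, predictions$labels)
  n_drop <- (length(cs_data$label) - length(common)) +
    (length(predictions$labels) - length(common))
  if (length(common) == 0L) abort("no common chemical-shift labels")
  if (n_drop > 0L)
    warn(paste0(n_drop, " chemical-shift label(s) without a match were dropped"))
  ei <- match(common, cs_data$label)
  pi <- match(common, predictions$labels)
  list(cs_data = cs_data[ei, ],
       cs_pred = predictions$cs_pred[, pi, drop = FALSE],
       cs_pred_err = if (!is.null(predictions$cs_pred_err))
         predictions$cs_pred_err[pi])
}

#' Construct an ensemble model
#'
#' The point-estimate result of variational model selection: the retained
#' conformers, their population weights (on the simplex), the final
#' variational objective and the SAXS scale factor.
#'
#' @param member_ids Character ids of the retained conformers.
#' @param weights Population weights; non-negative, summing to 1 within
#'   1e-9.
#' @param L_value Final value of the variational objective (lower better).
#' @param lambda_hat SAXS scale factor.
#' @param u_ref Optional energy-prior reference-shift hyperparameter.
#' @param alpha Optional final Dirichlet concentration parameters.
#' @param ... Further metadata stored as-is (e.g. `history`, `fitted`).
#' @return Object of class `ensemble_model`.
#' @export
ensemble_model <- function(member_ids, weights, L_value = NA_real_,
                           lambda_hat = NA_real_, u_ref = NULL,
                           alpha = NULL, ...) {
  member_ids <- as.character(member_ids)
  weights <- as.numeric(weights)
  if (length(weights) != length(member_ids))
    abort("weights and member_ids must have equal length")
  if (any(weights < 0)) abort("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    abort(paste0("weights must sum to 1 within 1e-9 (got ",
                 format(sum(weights), digits = 12), ")"))
  structure(list(member_ids = member_ids, weights = weights,
                 L_value = L_value, lambda_hat = lambda_hat,
                 u_ref = u_ref, alpha = alpha, ...),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> ", length(x$member_ids), " members, L = ",
      format(x$L_value, digits = 6), ", lambda = ",
      format(x$lambda_hat, digits = 6), "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Construct a container of posterior draws
#'
#' @param w_draws Matrix of weight draws (draws x members), each row on
#'   the simplex within 1e-9; column names are member ids.
#' @param lambda_draws SAXS scale-factor draws.
#' @param chain_ids Integer chain index per draw; at least 2 chains.
#' @param uref_draws Optional energy-reference hyperparameter draws.
#' @param ... Metadata (diagnostics tibble, acceptance rates, ...).
#' @return Object of class `posterior_draws`.
#' @export
posterior_draws <- function(w_draws, lambda_draws, chain_ids,
                            uref_draws = NULL, ...) {
  w_draws <- as.matrix(w_draws)
  bad <- abs(rowSums(w_draws) - 1) > 1e-9
  if (any(bad)) abort("weight draws must lie on the simplex within 1e-9")
  if (any(w_draws < -1e-12)) abort("negative weight draw")
  if (length(unique(chain_ids)) < 2L)
    abort("at least 2 chains are required for split-Rhat")
  if (length(lambda_draws) != nrow(w_draws) ||
      length(chain_ids) != nrow(w_draws))
    abort("draw vectors must have one entry per draw")
  structure(list(w_draws = w_draws, lambda_draws = as.numeric(lambda_draws),
                 uref_draws = uref_draws, chain_ids = as.integer(chain_ids),
                 ...),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws> ", nrow(x$w_draws), " draws, ",
      length(unique(x$chain_ids)), " chains, ", ncol(x$w_draws),
      " ensemble members\n", sep = "")
  invisible(x)
}
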