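#' Morpho-functional indices of limb bones
#'
#' Three percent indices summarize the degree of development of digging-related
#' bone superstructures:
#'
#' * **RDT** — relative position of the deltoid tuberosity along the humerus:
#'   distance from the proximal end to the DT landmark over total humeral
#'   length, times 100. A more distal DT (larger RDT) lengthens the in-lever of
#'   arm retraction.
#' * **IFA** — index of fossorial ability: olecranon process length over the
#'   functional ulna length (total length minus olecranon), times 100. The
#'   classic proxy of forelimb digging capability.
#' * **TJI** — tibio-fibular junction index: distance from the proximal end of
#'   the tibia to the ossified tibio-fibular junction over total tibial length,
#'   times 100.
#'
#' All three are scale-invariant ratios of linear measurements in mm. When the
#' superstructure is absent (e.g. the naked mole-rat lacks a projected deltoid
#' tuberosity and a fused tibia-fibula) the index is missing (`NA`), never 0.
#'
#' @param humerus_length,dt_landmark Humeral total length and proximal-end to
#'   deltoid-tuberosity distance (mm).
#' @param olecranon_length,ulna_total_length Olecranon process length and ulna
#'   total length (mm).
#' @param tibia_length,junction_landmark Tibial total length and proximal-end
#'   to tibio-fibular junction distance (mm).
#' @param absent Logical; structure absent. Returns `NA_real_` for flagged
#'   elements. Recycled.
#' @return Numeric vector of index values (percent).
#' @examples
#' compute_rdt(40, 20)  # mid-shaft DT -> 50
#' compute_ifa(10, 50)  # -> 25
#' compute_tji(30, 15)  # -> 50
#' @name indices
NULL

#' @rdname indices
#' @export
compute_rdt <- function(humerus_length, dt_landmark, absent = FALSE) {
  proportion_index(dt_landmark, humerus_length, absent, "RDT")
}

#' @rdname indices
#' @export
compute_tji <- function(tibia_length, junction_landmark, absent = FALSE) {
  proportion_index(junction_landmark, tibia_length, absent, "TJI")
}

#' @rdname indices
#' @export
compute_ifa <- function(olecranon_length, ulna_total_length, absent = FALSE) {
  n <- max(length(olecranon_length), length(ulna_total_length), length(absent))
  ole <- rep_len(olecranon_length, n)
  tot <- rep_len(ulna_total_length, n)
  absent <- rep_len(as.logical(absent), n)
  live <- !absent
  if (any(live & (!is.finite(tot) | tot <= 0))) {
    abort("IFA: ulna total length must be positive")
  }
  if (any(live & (ole <= 0 | ole >= tot), na.rm = TRUE)) {
    abort("IFA: olecranon length must lie strictly between 0 and the ulna total length")
  }
  out <- ole / (tot - ole) * 100
  out[absent] <- NA_real_
  out
}

#' @keywords internal
proportion_index <- function(landmark, total, absent, label) {
  n <- max(length(landmark), length(total), length(absent))
  landmark <- rep_len(landmark, n)
  total <- rep_len(total, n)
  absent <- rep_len(as.logical(absent), n)
  live <- !absent
  if (any(live & (!is.finite(total) | total <= 0))) {
    abort(paste0(label, ": total length must be positive"))
  }
  if (any(live & (landmark < 0 | landmark > total), na.rm = TRUE)) {
    abort(paste0(label, ": landmark distance must lie in [0, total length]"))
  }
  out <- landmark / total * 100
  out[absent] <- NA_real_
  out
}

#' Compute index records from a raw bone-measurement table
#'
#' Maps each measured bone to its index: humerus -> RDT, ulna -> IFA,
#' tibia-fibula -> TJI (femur rows carry no index and are dropped). Rows with
#' the structure-absent flag set yield a missing index value, preserving the
#' record so downstream exclusion is explicit.
#'
#' @param measurements Data frame with columns `specimen_id`, `species`,
#'   `body_mass_g`, `bone` (one of `"humerus"`, `"ulna"`, `"femur"`,
#'   `"tibia-fibula"`), `total_length_mm`, `landmark_mm`, `landmark_absent`
#'   (0/1 or logical). Extra columns (`sex`, `age_class`, ...) pass through
#'   untouched.
#' @return A tibble of index records: `specimen_id`, `species`, `index`,
#'   `value` (percent, `NA` when the superstructure is absent), `body_mass_g`.
#' @export
compute_indices <- function(measurements) {
  req <- c("specimen_id", "species", "body_mass_g", "bone",
           "total_length_mm", "landmark_mm", "landmark_absent")
  miss <- setdiff(req, names(measurements))
  if (length(miss) > 0L) {
    abort(paste0("measurements table missing column(s): ", paste(miss, collapse = ", ")))
  }
  m <- tibble::as_tibble(measurements)
  m$landmark_absent <- as.logical(m$landmark_absent)
  bone_index <- c(humerus = "RDT", ulna = "IFA", `tibia-fibula` = "TJI")
  m <- dplyr::filter(m, .data$bone %in% names(bone_index))
  value <- numeric(nrow(m))
  for (b in unique(m$bone)) {
    i <- which(m$bone == b)
    value[i] <- switch(b,
      humerus        = compute_rdt(m$total_length_mm[i], m$landmark_mm[i], m$landmark_absent[i]),
      ulna           = compute_ifa(m$landmark_mm[i], m$total_length_mm[i], m$landmark_absent[i]),
      `tibia-fibula` = compute_tji(m$total_length_mm[i], m$landmark_mm[i], m$landmark_absent[i])
    )
  }
  tibble::tibble(
    specimen_id = m$specimen_id,
    species = trimws(as.character(m$species)),
    index = unname(bone_index[m$bone]),
    value = value,
    body_mass_g = m$body_mass_g
  )
}

#' Build a regression-ready dataset for one index
#'
#' Filters the index records to one index, drops rows with a missing index
#' value (this implements the exclusion of species lacking the superstructure,
#' e.g. the naked mole-rat for RDT and TJI), log-transforms, and centers log
#' body mass at the retained-rows mean. Species are coded by their tip order
#' in the supplied tree.
#'
#' @param records Index-record tibble as produced by [compute_indices()] (or
#'   any data frame with `specimen_id`, `species`, `index`, `value`,
#'   `body_mass_g`).
#' @param index One of `"RDT"`, `"IFA"`, `"TJI"`.
#' @param tree `phylo` whose tips cover every retained species; tips without
#'   data are pruned from the stored tree.
#' @return Object of class `regression_dataset`: list with `data` (tibble:
#'   `specimen_id`, `species`, `species_idx`, `x` centered log body mass, `y`
#'   log index), `index`, `species` (tip-ordered retained species),
#'   `center_log_bm` (the centering constant, natural-log grams), `n`, and
#'   `tree` (the input tree pruned to the retained species).
#' @details Natural logarithms are used throughout; body mass is in grams.
#'   An error is raised if a retained species is not a tip of `tree`, or if
#'   all rows are dropped.
#' @export
build_dataset <- function(records, index, tree) {
  index <- match.arg(index, c("RDT", "IFA", "TJI"))
  r <- tibble::as_tibble(records)
  r <- dplyr::filter(r, .data$index == !!index)
  if (nrow(r) == 0L) abort(paste0("no records for index ", index))
  r <- dplyr::filter(r, !is.na(.data$value))
  if (nrow(r) == 0L) abort(paste0("all rows for index ", index, " have missing values"))
  if (any(!is.finite(r$body_mass_g) | r$body_mass_g <= 0)) {
    abort("body mass must be present and positive for every retained row")
  }
  tree <- validate_tree(tree)
  missing_sp <- setdiff(unique(r$species), tree$tip.label)
  if (length(missing_sp) > 0L) {
    abort(paste0("species not in tree: ", paste(missing_sp, collapse = ", ")))
  }
  keep <- intersect(tree$tip.label, unique(r$species))
  tr <- if (length(keep) < ape::Ntip(tree)) ape::keep.tip(tree, keep) else tree
  species <- tr$tip.label
  x_raw <- log(r$body_mass_g)
  center <- mean(x_raw)
  sp_idx <- match(r$species, species)
  data <- tibble::tibble(
    specimen_id = r$specimen_id,
    species = r$species,
    species_idx = sp_idx,
    x = x_raw - center,
    y = log(r$value)
  )
  structure(
    list(data = data, index = index, species = species,
         center_log_bm = center, n = nrow(data), tree = tr),
    class = "regression_dataset"
  )
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat(sprintf("<regression_dataset> index %s: %d individuals, %d species\n",
              x$index, x$n, length(x$species)))
  cat("  centering constant (mean log body mass, g):",
      format(x$center_log_bm, digits = 6), "\n")
  invisible(x)
}
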