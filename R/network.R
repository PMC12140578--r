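#' Scout atlas
#'
#' Loads an atlas file naming the scouts with hemisphere and lobe labels and
#' named region sets.  The packaged default emulates the 62-scout Mindboggle
#' cortical parcellation (31 regions per hemisphere) and defines
#' `frontal_left` / `frontal_right` as all frontal-lobe scouts of the
#' respective hemisphere (motor and orbitofrontal scouts included); the file
#' is plain JSON and can be edited to change the region membership without
#' touching code.
#'
#' @param path path to an atlas JSON file; default is the packaged 62-scout
#'   atlas.
#' @return an object of class `scout_atlas`: list with `scout_names`,
#'   `hemisphere`, `lobe`, `region_sets`.
#' @export
load_atlas <- function(path = system.file("extdata", "mindboggle62.json",
                                          package = "icnet")) {
  a <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- as.data.frame(a$scouts)
  if (anyDuplicated(sc$name)) stop_config("atlas scout names must be unique")
  rs <- lapply(a$region_sets, as.character)
  for (nm in names(rs)) {
    missing <- setdiff(rs[[nm]], sc$name)
    if (length(missing)) {
      stop_config("region set '", nm, "' references unknown scouts: ",
                  paste(missing, collapse = ", "))
    }
    if (!length(rs[[nm]])) stop_config("region set '", nm, "' is empty")
  }
  structure(list(scout_names = sc$name, hemisphere = sc$hemisphere,
                 lobe = sc$lobe, region_sets = rs),
            class = "scout_atlas")
}

#' Weighted node degree
#'
#' The weighted node degree (wND) of a scout is the sum of its imaginary
#' coherence with all other scouts -- the row sums of the zero-diagonal IC
#' matrix.  It measures the overall importance ("hub-ness") of a scout in
#' the coherence network.
#'
#' @param icm an `ic_matrix` from [band_ic()], or a plain symmetric
#'   zero-diagonal matrix.
#' @return named numeric vector of per-scout wND values (>= 0).
#' @export
weighted_node_degree <- function(icm) {
  m <- if (inherits(icm, "ic_matrix")) icm$ic else icm
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop_input("need a square IC matrix")
  d <- m
  diag(d) <- 0
  rowSums(d, na.rm = TRUE)
}

#' z-normalize wND over scouts
#'
#' Centers and scales the wND values across all scouts: `z_i = (wnd_i -
#' mean) / sd`, using the sample standard deviation (n - 1).  All-equal wND
#' is a degenerate input and raises a typed error (the pipeline records a
#' missing value in that case).
#'
#' @param wnd numeric vector of wND values (>= 2 scouts).
#' @return numeric vector of z-scores (mean 0, sd 1).
#' @export
z_normalize <- function(wnd) {
  if (length(wnd) < 2L) stop_input("z-normalization needs >= 2 scouts")
  s <- stats::sd(wnd)
  if (!is.finite(s) || s == 0) {
    stop_degenerate("zero wND standard deviation: z-scores undefined")
  }
  (wnd - mean(wnd)) / s
}

#' Mean z-scored wND over an atlas region
#'
#' @param z named numeric vector of z-scored wND per scout.
#' @param atlas a `scout_atlas`.
#' @param region name of a region set defined in the atlas.
#' @return scalar unweighted mean of `z` over the region's scouts.
#' @export
region_mean <- function(z, atlas, region) {
  stopifnot(inherits(atlas, "scout_atlas"))
  if (!region %in% names(atlas$region_sets)) {
    stop_config("unknown region '", region, "'")
  }
  members <- atlas$region_sets[[region]]
  missing <- setdiff(members, names(z))
  if (length(missing)) {
    stop_config("region '", region, "' scouts absent from data: ",
                paste(missing, collapse = ", "))
  }
  mean(z[members])
}

#' Network metrics of one IC matrix
#'
#' Convenience wrapper: wND, z-scored wND and the atlas region means, in the
#' order the pipeline uses (z-normalize first, then average regions on the
#' z-scores).  Degenerate wND (zero spread) yields `NA` z-scores and region
#' means with a warning instead of an error.
#'
#' @param icm an `ic_matrix`.
#' @param atlas a `scout_atlas`, or `NULL` to skip region averaging.
#' @return list with `wnd`, `z`, `region_means`.
#' @export
network_metrics <- function(icm, atlas = NULL) {
  wnd <- weighted_node_degree(icm)
  z <- tryCatch(z_normalize(wnd), icnet_degenerate_error = function(e) {
    warning(conditionMessage(e), "; recording missing values")
    stats::setNames(rep(NA_real_, length(wnd)), names(wnd))
  })
  rm_ <- NULL
  if (!is.null(atlas)) {
    rm_ <- vapply(names(atlas$region_sets), function(r) {
      if (anyNA(z)) NA_real_ else region_mean(z, atlas, r)
    }, numeric(1))
  }
  list(wnd = wnd, z = z, region_means = rm_)
}

#' Change scores: post-pre deltas and the condition difference
#'
#' From per-subject, per-condition, per-timepoint region metrics, computes
#' the post-pre delta within each condition and the difference of deltas
#' between conditions -- the "wND change", `(post_tRNS - pre_tRNS) -
#' (post_sham - pre_sham)` -- and, from per-condition behavioral scores, the
#' tRNS-sham behavioral change per task and measure.  Subjects missing any
#' of the four recording cells (or either behavioral condition) are excluded
#' with a warning.
#'
#' @param network data.frame with columns `subject`, `condition`
#'   (`"tRNS"`/`"sham"`), `timepoint` (`"pre"`/`"post"`), `region`, `value`.
#' @param behavior optional data.frame with columns `participant`,
#'   `condition`, `task`, `measure`, `value`.
#' @return object of class `change_table`: list with `network` (subject,
#'   region, delta_tRNS, delta_sham, wnd_change) and `behavior` (participant,
#'   task, measure, change) data.frames.
#' @export
change_scores <- function(network, behavior = NULL) {
  need <- c("subject", "condition", "timepoint", "region", "value")
  if (!all(need %in% names(network))) {
    stop_input("`network` needs columns ", paste(need, collapse = ", "))
  }
  out <- list()
  rows <- list(); excluded <- character()
  for (s in unique(network$subject)) {
    for (r in unique(network$region)) {
      sel <- network[network$subject == s & network$region == r, ]
      cell <- function(cond, tp) {
        v <- sel$value[sel$condition == cond & sel$timepoint == tp]
        if (length(v) != 1L) NA_real_ else v
      }
      v <- c(cell("tRNS", "post"), cell("tRNS", "pre"),
             cell("sham", "post"), cell("sham", "pre"))
      if (anyNA(v)) { excluded <- union(excluded, s); next }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, region = r,
        delta_tRNS = v[1L] - v[2L], delta_sham = v[3L] - v[4L],
        wnd_change = (v[1L] - v[2L]) - (v[3L] - v[4L]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(excluded)) {
    warning("excluded subject(s) with incomplete recording cells: ",
            paste(excluded, collapse = ", "))
  }
  out$network <- if (length(rows)) do.call(rbind, rows) else NULL

  if (!is.null(behavior)) {
    needb <- c("participant", "condition", "task", "measure", "value")
    if (!all(needb %in% names(behavior))) {
      stop_input("`behavior` needs columns ", paste(needb, collapse = ", "))
    }
    brows <- list(); bexcl <- character()
    keys <- unique(behavior[c("participant", "task", "measure")])
    for (k in seq_len(nrow(keys))) {
      sel <- behavior[behavior$participant == keys$participant[k] &
                        behavior$task == keys$task[k] &
                        behavior$measure == keys$measure[k], ]
      vt <- sel$value[sel$condition == "tRNS"]
      vs <- sel$value[sel$condition == "sham"]
      if (length(vt) != 1L || length(vs) != 1L || anyNA(c(vt, vs))) {
        bexcl <- union(bexcl, keys$participant[k]); next
      }
      brows[[length(brows) + 1L]] <- data.frame(
        participant = keys$participant[k], task = keys$task[k],
        measure = keys$measure[k], change = vt - vs, stringsAsFactors = FALSE)
    }
    if (length(bexcl)) {
      warning("excluded participant(s) with incomplete behavioral cells: ",
              paste(bexcl, collapse = ", "))
    }
    out$behavior <- if (length(brows)) do.call(rbind, brows) else NULL
  }
  structure(out, class = "change_table")
}
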