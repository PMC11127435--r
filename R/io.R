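# File interchange.
#
# Keypoint sequences travel as flat-triplet JSON ([x, y, v] per joint,
# COCO-keypoints style) or long-format CSV (t, person_id, joint, x, y,
# visible, label). Rendered scenes use a raw little-endian float64
# array container with a JSON sidecar describing the layout. Models and
# reports serialize to JSON.

#' Write motions as keypoint JSON
#'
#' One record per person; each frame holds a flat \code{[x, y, v]}
#' triplet list over joints (v is 1 for visible, 0 otherwise).
#'
#' @param motions list of \linkS4class{MotionSequence} (a bare sequence
#'   is accepted).
#' @param path output file.
#' @export
writeKeypointsJSON <- function(motions, path) {
  if (is(motions, "MotionSequence")) motions <- list(motions)
  persons <- lapply(motions, function(m) {
    frames <- lapply(seq_len(nFrames(m)), function(i) {
      kp <- rbind(m@coords[i, , 1L], m@coords[i, , 2L],
                  as.numeric(m@visible[i, ]))
      list(t = m@t[i], keypoints = as.numeric(kp))
    })
    list(person_id = m@personId, label = m@label, fps = m@fps,
         frames = frames)
  })
  obj <- list(format = "kinepose-keypoints-1", persons = persons)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              na = "null"), path)
  invisible(path)
}

#' Read keypoint JSON
#'
#' @param path file written by \code{\link{writeKeypointsJSON}}.
#' @return list of \linkS4class{MotionSequence}.
#' @export
readKeypointsJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "kinepose-keypoints-1"))
    .stopf("'%s' is not a kinepose keypoints file", path)
  lapply(obj$persons, function(p) {
    nT <- length(p$frames)
    nJ <- length(p$frames[[1L]]$keypoints) / 3L
    co <- array(NA_real_, dim = c(nT, nJ, 2L))
    vis <- matrix(TRUE, nT, nJ)
    tIdx <- integer(nT)
    for (i in seq_len(nT)) {
      kp <- matrix(as.numeric(unlist(p$frames[[i]]$keypoints)), nrow = 3L)
      co[i, , 1L] <- kp[1L, ]
      co[i, , 2L] <- kp[2L, ]
      vis[i, ] <- kp[3L, ] > 0
      tIdx[i] <- p$frames[[i]]$t
    }
    lab <- if (is.null(p$label)) NA_character_ else p$label
    MotionSequence(co, t = tIdx, visible = vis, personId = p$person_id,
                   label = lab, fps = if (is.null(p$fps)) 20 else p$fps)
  })
}

#' Write motions as long-format CSV
#'
#' Columns \code{t, person_id, joint, x, y, visible, label}; joint
#' indices are 0-based.
#'
#' @param motions list of \linkS4class{MotionSequence}.
#' @param path output file.
#' @export
writeKeypointsCSV <- function(motions, path) {
  if (is(motions, "MotionSequence")) motions <- list(motions)
  rows <- do.call(rbind, lapply(motions, function(m) {
    nT <- nFrames(m); nJ <- nJoints(m)
    data.frame(t = rep(m@t, each = nJ),
               person_id = m@personId,
               joint = rep(0:(nJ - 1L), nT),
               x = as.numeric(t(m@coords[, , 1L])),
               y = as.numeric(t(m@coords[, , 2L])),
               visible = as.integer(t(m@visible)),
               label = m@label)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read long-format keypoint CSV
#'
#' @param path file written by \code{\link{writeKeypointsCSV}}.
#' @return list of \linkS4class{MotionSequence}.
#' @export
readKeypointsCSV <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$person_id), function(d) {
    tIdx <- sort(unique(d$t))
    nJ <- max(d$joint) + 1L
    co <- array(NA_real_, dim = c(length(tIdx), nJ, 2L))
    vis <- matrix(TRUE, length(tIdx), nJ)
    for (i in seq_along(tIdx)) {
      di <- d[d$t == tIdx[i], ]
      di <- di[order(di$joint), ]
      co[i, , 1L] <- di$x
      co[i, , 2L] <- di$y
      vis[i, ] <- di$visible > 0
    }
    MotionSequence(co, t = tIdx, visible = vis,
                   personId = d$person_id[1L],
                   label = as.character(d$label[1L]), fps = 20)
  })
}

#' Write a rendered scene to an array container
#'
#' Writes \code{<prefix>.bin} -- the confidence maps, affinity fields,
#' mask and per-person truth coordinates as consecutive little-endian
#' float64 blocks in R column order -- and \code{<prefix>.json}, a
#' sidecar with the array dimensions, grid layout (origin top-left, x
#' rightward, y downward) and rendering parameters. The round trip
#' through \code{\link{readScene}} is bit-identical.
#'
#' @param scene a \linkS4class{FieldScene}.
#' @param prefix output path without extension.
#' @export
writeScene <- function(scene, prefix) {
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(scene@confMaps), con, size = 8L, endian = "little")
  writeBin(as.numeric(scene@pafFields), con, size = 8L, endian = "little")
  writeBin(as.numeric(scene@mask), con, size = 8L, endian = "little")
  # truth coordinates go into the binary container too, so the round
  # trip is exact to the bit
  for (f in scene@truth)
    writeBin(as.numeric(f@coords), con, size = 8L, endian = "little")
  p <- scene@params
  sidecar <- list(
    format = "kinepose-scene-1",
    layout = paste("float64 blocks (conf_maps, paf_fields, mask, then one",
                   "J x 2 coords block per truth person), column-major per",
                   "array; grid origin top-left, x rightward, y downward"),
    dims = list(conf_maps = dim(scene@confMaps),
                paf_fields = dim(scene@pafFields),
                mask = dim(scene@mask)),
    params = list(grid_w = p@gridW, grid_h = p@gridH, sigma = p@sigma,
                  limb_width = p@limbWidth, n_persons = p@nPersons,
                  noise_sd = p@noiseSd, seed = p@seed),
    truth = lapply(scene@truth, function(f)
      list(person_id = f@personId, t = f@t, n_joints = nrow(f@coords),
           visible = as.integer(f@visible))))
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE, digits = NA),
             paste0(prefix, ".json"))
  invisible(prefix)
}

#' Read a scene container
#'
#' @param prefix path prefix used by \code{\link{writeScene}}.
#' @return a \linkS4class{FieldScene}.
#' @export
readScene <- function(prefix) {
  sc <- jsonlite::fromJSON(paste0(prefix, ".json"), simplifyVector = FALSE)
  if (!identical(sc$format, "kinepose-scene-1"))
    .stopf("'%s.json' is not a kinepose scene sidecar", prefix)
  dims <- lapply(sc$dims, function(d) unlist(d))
  n1 <- prod(dims$conf_maps); n2 <- prod(dims$paf_fields); n3 <- prod(dims$mask)
  nT <- sum(vapply(sc$truth, function(fr) 2L * fr$n_joints, integer(1L)))
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = n1 + n2 + n3 + nT, size = 8L,
               endian = "little")
  at <- n1 + n2 + n3
  truth <- lapply(sc$truth, function(fr) {
    co <- matrix(v[at + seq_len(2L * fr$n_joints)], ncol = 2L)
    at <<- at + 2L * fr$n_joints
    SkeletonFrame(co, personId = fr$person_id, t = fr$t,
                  visible = unlist(fr$visible) > 0)
  })
  p <- sc$params
  new("FieldScene",
      confMaps = array(v[seq_len(n1)], dim = dims$conf_maps),
      pafFields = array(v[n1 + seq_len(n2)], dim = dims$paf_fields),
      mask = array(v[n1 + n2 + seq_len(n3)], dim = dims$mask),
      truth = truth,
      params = SceneParams(p$grid_w, p$grid_h, p$sigma, p$limb_width,
                           p$n_persons, p$noise_sd, p$seed))
}

#' Write assembled skeletons with their scores
#'
#' Same keypoint triplet dialect as \code{\link{writeKeypointsJSON}},
#' plus per-joint peak scores and the accepted limb reliabilities.
#'
#' @param skels list of \linkS4class{AssembledSkeleton}.
#' @param path output file.
#' @export
writeSkeletonsJSON <- function(skels, path) {
  obj <- list(format = "kinepose-skeletons-1",
              skeletons = lapply(skels, function(s) {
                kp <- rbind(s@coords[, 1L], s@coords[, 2L],
                            as.numeric(!is.na(s@scores)))
                kp[is.na(kp)] <- -1
                list(keypoints = as.numeric(kp),
                     scores = ifelse(is.na(s@scores), -1, s@scores),
                     limbs = s@limbs)
              }))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Write / read a fitted PCA model as JSON
#'
#' @param model a \linkS4class{PCAModel}.
#' @param path JSON file.
#' @export
writePCAModel <- function(model, path) {
  obj <- list(format = "kinepose-pca-1", mean = model@center,
              eigvals = model@eigvals, eigvecs = model@eigvecs,
              selected = model@selected, precision = model@precision,
              mode = model@mode)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname writePCAModel
#' @export
readPCAModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$format, "kinepose-pca-1"))
    .stopf("'%s' is not a kinepose PCA file", path)
  vecs <- matrix(obj$eigvecs, ncol = length(obj$eigvals))
  sel <- as.integer(obj$selected)
  red <- if (obj$mode == "standard") vecs[, sel, drop = FALSE] else
    vecs[, sel, drop = FALSE] %*% diag(obj$eigvals[sel], nrow = length(sel))
  new("PCAModel", center = obj$mean, eigvals = obj$eigvals, eigvecs = vecs,
      selected = sel, reduction = red, precision = obj$precision,
      mode = obj$mode)
}

#' Export Procrustes transforms as JSON
#'
#' @param transforms list of \linkS4class{ProcrustesTransform}.
#' @param path JSON file.
#' @export
writeTransformsJSON <- function(transforms, path) {
  obj <- list(format = "kinepose-transforms-1",
              transforms = lapply(transforms, function(tr)
                list(translation = tr@translation, scales = tr@scales,
                     theta = tr@theta, pd2 = tr@pd2)))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Write a labelled feature table as CSV
#'
#' Column names document the coefficient ordering
#' (\code{<segment>_<axis>_c<k>} then \code{<segment>_<axis>_r2});
#' the label column is last.
#'
#' @param x feature matrix with column names; \code{labels} class
#'   tokens.
#' @param labels class tokens, one per row.
#' @param path output file.
#' @export
writeFeatureCSV <- function(x, labels, path) {
  df <- as.data.frame(x)
  df$label <- labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  list(x = as.matrix(df[, setdiff(names(df), "label"), drop = FALSE]),
       labels = as.character(df$label))
}

#' Persist / restore a trained classifier
#'
#' Writes \code{<prefix>.json} (human-readable metadata: classes,
#' kernel settings, standardization) and \code{<prefix>.rds} (the full
#' fitted object, a binary container).
#'
#' @param model an \linkS4class{SVMEnsemble} or \linkS4class{MLPModel}.
#' @param prefix output path without extension.
#' @export
saveClassifier <- function(model, prefix) {
  meta <- if (is(model, "SVMEnsemble"))
    list(format = "kinepose-svm-1", classes = model@classes,
         kernel = model@kernel, cost = model@cost, gamma = model@gamma,
         center = model@center, scale = model@scale)
  else
    list(format = "kinepose-mlp-1", classes = model@classes,
         hidden = length(model@b1), center = model@center,
         scale = model@scale)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             paste0(prefix, ".json"))
  saveRDS(model, paste0(prefix, ".rds"))
  invisible(prefix)
}

#' @rdname saveClassifier
#' @export
loadClassifier <- function(prefix) readRDS(paste0(prefix, ".rds"))

#' Write an evaluation report
#'
#' \code{<prefix>.json} carries the confusion matrix, per-class and
#' macro metrics and the accuracy; \code{<prefix>.csv} the per-class
#' table.
#'
#' @param report a \linkS4class{ClassifierReport}.
#' @param prefix output path without extension.
#' @export
writeReport <- function(report, prefix) {
  obj <- list(format = "kinepose-report-1",
              classes = rownames(report@confusion),
              confusion = report@confusion,
              per_class = report@perClass,
              macro = as.list(report@macro),
              accuracy = report@accuracy)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              na = "null", dataframe = "columns"),
             paste0(prefix, ".json"))
  utils::write.csv(report@perClass, paste0(prefix, ".csv"),
                   row.names = FALSE)
  invisible(prefix)
}
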