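#' Backbone model for one chain segment
#'
#' An ordered set of per-residue backbone coordinates (N, CA, C, O) in
#' Angstrom. This is the unit that is built, rigidly moved, scored against
#' contact constraints, and written to PDB. Residue numbering is 1-based and
#' strictly increasing; gaps are allowed (unmodelled loops).
#'
#' @param resno integer vector of residue sequence numbers (strictly
#'   increasing, 1-based).
#' @param n,ca,c,o n x 3 coordinate matrices for the four backbone atoms.
#' @return An object of class `backbone_model`.
#' @export
backbone_model <- function(resno, n, ca, c, o) {
  resno <- as.integer(resno)
  n <- rbind(n); ca <- rbind(ca); c <- rbind(c); o <- rbind(o)
  nr <- length(resno)
  stopifnot(nrow(n) == nr, nrow(ca) == nr, nrow(c) == nr, nrow(o) == nr,
            ncol(ca) == 3)
  if (nr > 1 && any(diff(resno) <= 0)) {
    stop("residue numbers must be strictly increasing")
  }
  dimnames(n) <- dimnames(ca) <- dimnames(c) <- dimnames(o) <- NULL
  structure(list(resno = resno, n = n, ca = ca, c = c, o = o),
            class = "backbone_model")
}

#' @export
print.backbone_model <- function(x, ...) {
  cat(sprintf("<backbone_model> %d residues (%d-%d), %d backbone atoms\n",
              length(x$resno), min(x$resno), max(x$resno), 4L * length(x$resno)))
  invisible(x)
}

#' Number of residues in a backbone model
#' @param model a [backbone_model()].
#' @return Integer residue count.
#' @export
n_residues <- function(model) length(model$resno)

#' Alpha-carbon coordinates of a backbone model
#' @param model a [backbone_model()].
#' @return n x 3 matrix of CA coordinates (Angstrom), rows in residue order.
#' @export
ca_coords <- function(model) model$ca

#' Look up CA coordinates for specific residue numbers
#' @param model a [backbone_model()].
#' @param resno residue numbers to look up.
#' @return length(resno) x 3 matrix; rows are NA where a residue is absent.
#' @keywords internal
ca_at <- function(model, resno) {
  idx <- match(resno, model$resno)
  model$ca[idx, , drop = FALSE]
}

#' Apply a rigid transform to a backbone model
#' @param model a [backbone_model()].
#' @param transform a [rigid_transform()].
#' @return The transformed [backbone_model()].
#' @export
transform_model <- function(model, transform) {
  backbone_model(model$resno,
                 apply_transform(model$n, transform),
                 apply_transform(model$ca, transform),
                 apply_transform(model$c, transform),
                 apply_transform(model$o, transform))
}

#' Concatenate backbone models into one chain
#'
#' Residue numbering across the pieces must remain strictly increasing.
#'
#' @param models list of [backbone_model()] objects in sequence order.
#' @return A single [backbone_model()].
#' @export
bind_models <- function(models) {
  backbone_model(unlist(lapply(models, `[[`, "resno")),
                 do.call(rbind, lapply(models, `[[`, "n")),
                 do.call(rbind, lapply(models, `[[`, "ca")),
                 do.call(rbind, lapply(models, `[[`, "c")),
                 do.call(rbind, lapply(models, `[[`, "o")))
}

#' Extract a residue range from a backbone model
#' @param model a [backbone_model()].
#' @param first,last inclusive residue-number bounds.
#' @return A [backbone_model()] with the residues in `[first, last]`.
#' @export
slice_model <- function(model, first, last) {
  keep <- model$resno >= first & model$resno <= last
  if (!any(keep)) stop("no residues in requested range")
  backbone_model(model$resno[keep], model$n[keep, , drop = FALSE],
                 model$ca[keep, , drop = FALSE], model$c[keep, , drop = FALSE],
                 model$o[keep, , drop = FALSE])
}

#' @importFrom tibble as_tibble tibble
#' @export
as_tibble.backbone_model <- function(x, ...) {
  nr <- length(x$resno)
  xyz <- lapply(1:3, function(k) {
    as.vector(rbind(x$n[, k], x$ca[, k], x$c[, k], x$o[, k]))
  })
  tibble::tibble(
    resno = rep(x$resno, each = 4L),
    elety = rep(c("N", "CA", "C", "O"), nr),
    x = xyz[[1]], y = xyz[[2]], z = xyz[[3]]
  )
}

#' Write backbone models to a PDB file
#'
#' Models are written as poly-alanine with occupancy 1.00 and B-factor 0.00,
#' one chain per model. Multiple chains are written from a named list.
#'
#' @param model a [backbone_model()] or a named list of them (names are chain
#'   identifiers; a bare model is written as chain "A").
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  if (inherits(model, "backbone_model")) model <- list(A = model)
  if (is.null(names(model)) || any(!nzchar(names(model)))) {
    stop("multi-chain output requires a named list of models")
  }
  at <- do.call(rbind, lapply(names(model), function(ch) {
    df <- as.data.frame(as_tibble.backbone_model(model[[ch]]))
    df$chain <- ch
    df
  }))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno, resid = rep("ALA", nrow(at)),
    eleno = seq_len(nrow(at)), elety = at$elety, chain = at$chain,
    o = rep(1, nrow(at)), b = rep(0, nrow(at))
  )
  invisible(path)
}

#' Read backbone models from a PDB file
#'
#' Reads backbone atoms (N, CA, C, O) of each chain. Residues missing any of
#' the four backbone atoms are dropped with a warning.
#'
#' @param path PDB file path.
#' @return A named list of [backbone_model()] objects, one per chain.
#' @export
read_model_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom[pdb$atom$elety %in% c("N", "CA", "C", "O"), ]
  out <- list()
  for (ch in unique(at$chain)) {
    a <- at[at$chain == ch, ]
    cnt <- table(a$resno)
    full <- as.integer(names(cnt)[cnt == 4L])
    if (length(full) < length(cnt)) {
      warning(sprintf("chain %s: dropped %d residue(s) with incomplete backbone",
                      ch, length(cnt) - length(full)))
    }
    a <- a[a$resno %in% full, ]
    a <- a[order(a$resno, match(a$elety, c("N", "CA", "C", "O"))), ]
    getm <- function(ety) as.matrix(a[a$elety == ety, c("x", "y", "z")])
    out[[ch]] <- backbone_model(sort(full), getm("N"), getm("CA"),
                                getm("C"), getm("O"))
  }
  out
}

#' Write a model trajectory as a multi-model PDB
#'
#' Frames (e.g. from [interpolate_states()]) are written as MODEL/ENDMDL
#' blocks so molecular viewers play them as a movie. Interpolated frames are
#' geometric illustrations, not physical conformations; a REMARK records this.
#'
#' @param models list of [backbone_model()] objects with identical residues.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frames_pdb <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   interpolated frames: geometric illustration, non-physical", con)
  for (k in seq_along(models)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    df <- as.data.frame(as_tibble.backbone_model(models[[k]]))
    writeLines(sprintf(
      "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(df)), paste0(" ", df$elety), "", "ALA", "A", df$resno, "",
      df$x, df$y, df$z, 1, 0, substr(df$elety, 1, 1)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
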