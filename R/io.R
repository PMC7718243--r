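#' Write a simulated study to disk
#'
#' Layout: one NIfTI per B1 stack (frames in acquisition order, references
#' interleaved), a combined offset table CSV (file, frame index, B1,
#' offset, is_reference), the IR series as NIfTI with a TI CSV, the label
#' image and every truth map as NIfTI, and the protocol as YAML.
#'
#' @param study \code{\link{simulate_study}} output
#' @param dir output directory (created)
#' @return invisibly, the directory
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- list()
  for (nm in names(study$stacks)) {
    st <- study$stacks[[nm]]
    fn <- sprintf("zspec_b1_%s.nii.gz", gsub("[.]", "p", nm))
    RNifti::writeNifti(st$frames, file.path(dir, fn))
    tabs[[nm]] <- data.frame(file = fn, b1_ut = st$b1_ut, st$table)
  }
  utils::write.csv(do.call(rbind, tabs), file.path(dir, "offsets.csv"),
                   row.names = FALSE)
  RNifti::writeNifti(study$ir$frames, file.path(dir, "ir.nii.gz"))
  utils::write.csv(data.frame(ti_ms = study$ir$ti_ms),
                   file.path(dir, "ir_ti.csv"), row.names = FALSE)
  RNifti::writeNifti(study$label + 0, file.path(dir, "label.nii.gz"))
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (nm in names(study$truth))
    RNifti::writeNifti(study$truth[[nm]],
                       file.path(dir, "truth", paste0(nm, ".nii.gz")))
  proto <- study$protocol
  proto_l <- lapply(unclass(proto), function(x)
    if (is.list(x)) lapply(x, as.vector) else as.vector(x))
  proto_l$pool_offsets <- study$pool_offsets
  proto_l$pool_width <- as.list(study$pool_width)
  proto_l$seed <- study$seed
  yaml::write_yaml(proto_l, file.path(dir, "protocol.yaml"))
  invisible(dir)
}

#' Read a study written by \code{\link{write_study}}
#'
#' @param dir directory produced by \code{\link{write_study}}
#' @return \code{synthetic_study} object
#' @export
read_study <- function(dir) {
  tab <- utils::read.csv(file.path(dir, "offsets.csv"))
  py <- yaml::read_yaml(file.path(dir, "protocol.yaml"))
  proto <- protocol(
    b1_levels = as.numeric(py$b1_levels),
    offsets = stats::setNames(lapply(py$offsets, as.numeric),
                              names(py$offsets)),
    reference_offset_ppm = py$reference_offset_ppm,
    reference_every = py$reference_every, f0_mhz = py$f0_mhz,
    ti_ms = as.numeric(py$ti_ms), tr_ms = py$tr_ms,
    noise_sd = py$noise_sd, drift_slope = py$drift_slope,
    cest_b1_ut = as.numeric(py$cest_b1_ut), rician = isTRUE(py$rician))
  stacks <- list()
  for (fn in unique(tab$file)) {
    sub <- tab[tab$file == fn, ]
    nm <- as.character(sub$b1_ut[1])
    stacks[[nm]] <- list(
      b1_ut = sub$b1_ut[1],
      frames = array(RNifti::readNifti(file.path(dir, fn)),
                     dim = dim(RNifti::readNifti(file.path(dir, fn)))),
      table = data.frame(acq_index = sub$acq_index,
                         offset_ppm = sub$offset_ppm,
                         is_reference = as.logical(sub$is_reference)))
  }
  # preserve the original B1 ordering of the protocol
  stacks <- stacks[as.character(proto$b1_levels)]
  truth_files <- list.files(file.path(dir, "truth"), pattern = "nii")
  truth <- lapply(truth_files, function(f) {
    m <- RNifti::readNifti(file.path(dir, "truth", f))
    matrix(m, nrow(m), ncol(m))
  })
  names(truth) <- sub("[.]nii([.]gz)?$", "", truth_files)
  lab <- RNifti::readNifti(file.path(dir, "label.nii.gz"))
  ir <- RNifti::readNifti(file.path(dir, "ir.nii.gz"))
  pool_width <- unlist(py$pool_width)
  structure(list(label = matrix(as.integer(lab), nrow(lab), ncol(lab)),
                 truth = truth,
                 pool_offsets = as.numeric(py$pool_offsets),
                 pool_width = pool_width,
                 stacks = stacks,
                 ir = list(frames = array(ir, dim = dim(ir)),
                           ti_ms = as.numeric(py$ti_ms)),
                 protocol = proto, seed = py$seed),
            class = "synthetic_study")
}
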