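# Acquisition metadata. The microscope images carry no physical metadata
# we trust; pixel size, frame rate and substrate mechanics are config
# inputs, validated once at load.

#' Acquisition / assay configuration
#'
#' Bundle of acquisition metadata and substrate mechanics shared by the
#' assays. Pixel sizes and frame rates are never inferred from image
#' files; they must be supplied here.
#'
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param frame_interval_s Seconds between frames (> 0), for stacks.
#' @param substrate_modulus_pa Young's modulus of the substrate in Pa
#'   (default 10000, i.e. the 10 kPa polyacrylamide hydrogel).
#' @param poisson_ratio Substrate Poisson ratio in \[0, 0.5\]; default 0.5
#'   (incompressible polyacrylamide).
#' @param annulus_um Dilation distance around Z-disc pixels defining the
#'   sarcomeric compartment (default 0.65 um).
#' @param groove_axis_deg Orientation of the microgroove axis, degrees CCW
#'   from +x in \[0, 180).
#' @param rng_seed Optional integer seed recorded for reproducibility.
#' @return An `assay_config` object (named list).
#' @export
assay_config <- function(pixel_size_um = NULL,
                         frame_interval_s = NULL,
                         substrate_modulus_pa = 10000,
                         poisson_ratio = 0.5,
                         annulus_um = 0.65,
                         groove_axis_deg = 90,
                         rng_seed = NULL) {
  check_number(pixel_size_um, "pixel_size_um", min = 0, strict_min = TRUE,
               allow_null = TRUE)
  check_number(frame_interval_s, "frame_interval_s", min = 0,
               strict_min = TRUE, allow_null = TRUE)
  check_number(substrate_modulus_pa, "substrate_modulus_pa", min = 0,
               strict_min = TRUE)
  check_number(poisson_ratio, "poisson_ratio", min = 0, max = 0.5)
  check_number(annulus_um, "annulus_um", min = 0, strict_min = TRUE)
  check_number(groove_axis_deg, "groove_axis_deg", allow_null = TRUE)
  structure(list(pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 substrate_modulus_pa = substrate_modulus_pa,
                 poisson_ratio = poisson_ratio,
                 annulus_um = annulus_um,
                 groove_axis_deg = groove_axis_deg,
                 rng_seed = rng_seed),
            class = "assay_config")
}

#' Read an assay configuration from YAML
#'
#' Unknown keys are rejected so typos fail loudly; the resolved config is
#' logged.
#'
#' @param path Path to a flat-key YAML file.
#' @return An [assay_config()].
#' @export
read_assay_config <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_format("cannot parse YAML '%s': %s",
                                                  path, conditionMessage(e)))
  known <- names(formals(assay_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop_format("unknown config keys: %s",
                               paste(bad, collapse = ", "))
  cfg <- do.call(assay_config, raw)
  cq_log("loaded config %s: %s", path,
         paste(sprintf("%s=%s", names(unclass(cfg)),
                       vapply(unclass(cfg), function(v)
                         if (is.null(v)) "NULL" else format(v), "")),
               collapse = ", "))
  cfg
}

#' Write an assay configuration to YAML
#'
#' @param cfg An [assay_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "assay_config"))
  yaml::write_yaml(Filter(Negate(is.null), unclass(cfg)), path)
  invisible(path)
}
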