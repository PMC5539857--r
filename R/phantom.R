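#' Tissue layer specification
#'
#' One homogeneous layer of a layered phantom: the ground truth that the QUS
#' estimators are later asked to recover.
#'
#' @param name Layer label (e.g. "mucosa", "submucosa", "muscularis").
#' @param thickness Layer thickness in mm.
#' @param impedance Acoustic impedance in MRayl.
#' @param attenuation One-way amplitude attenuation coefficient in dB/mm.
#' @param backscatter_strength Dimensionless energy scale of the diffuse
#'   backscatter from sub-resolution scatterers; expected backscattered energy
#'   is proportional to this value.
#' @param scatterer_density Point-scatterer density in count/mm^2 (depth x
#'   lateral pitch plane).
#' @param sound_speed Longitudinal sound speed in m/s (default 1540, soft
#'   tissue).
#'
#' @return A `tissue_layer` list.
#' @export
tissue_layer <- function(name, thickness, impedance, attenuation = 0,
                         backscatter_strength = 0, scatterer_density = 0,
                         sound_speed = 1540) {
  assert_scalar_number(thickness, "thickness", positive = TRUE)
  assert_scalar_number(impedance, "impedance", positive = TRUE)
  assert_scalar_number(attenuation, "attenuation", nonneg = TRUE)
  assert_scalar_number(backscatter_strength, "backscatter_strength", nonneg = TRUE)
  assert_scalar_number(scatterer_density, "scatterer_density", nonneg = TRUE)
  assert_scalar_number(sound_speed, "sound_speed", positive = TRUE)
  structure(
    list(
      name = as.character(name), thickness = thickness, impedance = impedance,
      attenuation = attenuation, backscatter_strength = backscatter_strength,
      scatterer_density = scatterer_density, sound_speed = sound_speed
    ),
    class = "tissue_layer"
  )
}

#' Layered tissue phantom
#'
#' An ordered stack of homogeneous layers (superficial first) under a coupling
#' medium (degassed PBS / water), mounted on a substrate (agar over absorber).
#' All interface reflection coefficients must lie strictly inside (-1, 1).
#'
#' @param layers List of [tissue_layer()] objects, superficial first.
#' @param coupling_impedance Impedance of the coupling medium in MRayl
#'   (default 1.48, water/dPBS).
#' @param coupling_sound_speed Sound speed of the coupling medium in m/s
#'   (default 1480).
#' @param standoff Coupling path between transducer-side time origin and the
#'   tissue surface, in mm.
#' @param substrate_impedance Impedance of the backing substrate in MRayl
#'   (default 1.58, stiff agar).
#'
#' @return A `layered_phantom` list.
#' @examples
#' ph <- layered_phantom(list(
#'   tissue_layer("mucosa", 1.5, 1.60, attenuation = 1.86,
#'     backscatter_strength = 1, scatterer_density = 200),
#'   tissue_layer("submucosa", 1.5, 1.55, attenuation = 1.86,
#'     backscatter_strength = 0.8, scatterer_density = 200)
#' ))
#' @export
layered_phantom <- function(layers, coupling_impedance = 1.48,
                            coupling_sound_speed = 1480, standoff = 2,
                            substrate_impedance = 1.58) {
  if (inherits(layers, "tissue_layer")) layers <- list(layers)
  if (length(layers) < 1L) abort("A phantom needs at least one layer.")
  ok <- vapply(layers, inherits, logical(1), "tissue_layer")
  if (!all(ok)) abort("`layers` must be a list of tissue_layer objects.")
  assert_scalar_number(coupling_impedance, "coupling_impedance", positive = TRUE)
  assert_scalar_number(coupling_sound_speed, "coupling_sound_speed", positive = TRUE)
  assert_scalar_number(standoff, "standoff", nonneg = TRUE)
  assert_scalar_number(substrate_impedance, "substrate_impedance", positive = TRUE)
  z <- c(coupling_impedance, vapply(layers, `[[`, numeric(1), "impedance"),
         substrate_impedance)
  r <- diff(z) / (z[-1] + z[-length(z)])
  if (any(abs(r) >= 1)) abort("Interface reflection coefficients must lie in (-1, 1).")
  structure(
    list(
      layers = layers, coupling_impedance = coupling_impedance,
      coupling_sound_speed = coupling_sound_speed, standoff = standoff,
      substrate_impedance = substrate_impedance
    ),
    class = "layered_phantom"
  )
}

#' @export
print.layered_phantom <- function(x, ...) {
  cat(sprintf(
    "<layered_phantom> %d layer(s), standoff %.2f mm, Z_w = %.3f MRayl\n",
    length(x$layers), x$standoff, x$coupling_impedance
  ))
  print(tidy(x))
  invisible(x)
}

#' @describeIn layered_phantom One row per layer (name, thickness, impedance,
#'   attenuation, backscatter strength, scatterer density, sound speed).
#' @param x A `layered_phantom`.
#' @param ... Unused.
#' @method tidy layered_phantom
#' @export
tidy.layered_phantom <- function(x, ...) {
  purrr::map_dfr(x$layers, function(l) {
    tibble(
      name = l$name, thickness_mm = l$thickness, impedance_mrayl = l$impedance,
      attenuation_db_mm = l$attenuation,
      backscatter_strength = l$backscatter_strength,
      scatterer_density_mm2 = l$scatterer_density,
      sound_speed_m_s = l$sound_speed
    )
  })
}

# interface bookkeeping shared by the simulator: depth (mm), one-way travel
# time (s) to each interface, impedance on both sides
phantom_interfaces <- function(phantom) {
  layers <- phantom$layers
  th <- vapply(layers, `[[`, numeric(1), "thickness")
  cs <- vapply(layers, `[[`, numeric(1), "sound_speed")
  z <- c(phantom$coupling_impedance, vapply(layers, `[[`, numeric(1), "impedance"),
         phantom$substrate_impedance)
  depth <- phantom$standoff + c(0, cumsum(th))
  # one-way travel times: coupling path then each layer
  seg_time <- c(phantom$standoff * 1e-3 / phantom$coupling_sound_speed, th * 1e-3 / cs)
  time <- cumsum(seg_time)
  tibble(
    depth_mm = depth,
    time_one_way_s = time,
    z_above = z[-length(z)],
    z_below = z[-1]
  )
}
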