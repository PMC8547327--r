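# Shared physical constants. Whole blood density couples the gravimetric
# flow estimate to the simulator's mass synthesis, so it lives in exactly
# one place.

#' Density of whole blood
#'
#' Density used to convert balance mass readings (g) to perfused volume (mL),
#' i.e. 1 g corresponds to 1/1.06 mL of blood. Shared by the flow-analysis
#' and simulation components.
#'
#' @format A numeric scalar, g/mL.
#' @export
BLOOD_DENSITY_G_PER_ML <- 1.06

# The wall-shear design formula gamma = 100 Q / (H^2 W) takes Q in mL/min and
# H, W in mm. The constant 100 is 6 * (1000/60): the parallel-plate result
# gamma = 6 Q / (w h^2) after converting mL/min to mm^3/s.
.SHEAR_CONSTANT <- 100
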