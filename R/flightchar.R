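# Per-event flight characteristics: circle geometry, banking angle, lift,
# drag, sink rate relative to the air, and thermal strength.

#' Default aerodynamic parameters for soaring white storks
#'
#' Non-induced drag coefficient 0.033, induced drag factor 0.81, wing area
#' 0.57 m^2, aspect ratio 7.21, mass 3.63 kg, air density 1.15 kg/m^3,
#' gravitational acceleration 9.81 m/s^2.
#'
#' @param cd_ni,k_ind,s_wing,aspect_ratio,mass,rho,g_a override any default.
#' @return Named list of class `aero_params`.
#' @export
stork_params <- function(cd_ni = 0.033, k_ind = 0.81, s_wing = 0.57,
                         aspect_ratio = 7.21, mass = 3.63, rho = 1.15,
                         g_a = 9.81) {
  p <- list(cd_ni = cd_ni, k_ind = k_ind, s_wing = s_wing,
            aspect_ratio = aspect_ratio, mass = mass, rho = rho, g_a = g_a)
  if (any(unlist(p) <= 0)) stop("all aerodynamic parameters must be positive")
  class(p) <- "aero_params"
  p
}

#' Mean vertical ground speed over a window
#'
#' Endpoint height difference over elapsed time,
#' `(z[n] - z[1]) / ((n - 1) dt)`; positive for climb.
#'
#' @param z heights at the window fixes, metres (length n >= 3).
#' @param dt sampling interval, seconds.
#' @return Vertical ground speed, m/s.
#' @export
vertical_ground_speed <- function(z, dt) {
  n <- length(z)
  if (n < 3) stop("need a window of at least 3 heights")
  (z[n] - z[1]) / ((n - 1) * dt)
}

#' Circle geometry from the cumulative turn
#'
#' Mean angular rate `omega = |sum of turn angles| / elapsed time`, circle
#' radius `r = a_hat / omega`, and time per full circle `2 pi / omega`,
#' assuming steady circling at constant airspeed.
#'
#' @inheritParams airspeeds
#' @param w_hat estimated wind vector, m/s.
#' @param a_hat estimated mean airspeed, m/s.
#' @param dt sampling interval, seconds.
#' @return List with `omega` (rad/s), `radius` (m), `circle_time` (s).
#' @export
circle_geometry <- function(G, w_hat, a_hat, dt) {
  ang <- turn_angles(G, w_hat)
  dcum <- sum(ang)
  if (dcum == 0) stop("zero cumulative turn; circle geometry undefined")
  omega <- abs(dcum) / (length(ang) * dt)
  list(omega = omega, radius = a_hat / omega, circle_time = 2 * pi / omega)
}

#' Banking angle and lift acceleration in a balanced turn
#'
#' In a balanced turn the centripetal acceleration is `a_hat * omega =
#' (L/m) sin(beta)` and gravity is `(L/m) cos(beta)`, giving
#' `beta = atan(a_hat omega / g)` and `L/m = sqrt(g^2 + a_hat^2 omega^2)`.
#'
#' @param a_hat mean airspeed, m/s.
#' @param omega angular rate, rad/s.
#' @param params [stork_params()] aerodynamic parameters.
#' @return List with `beta` (radians) and `lift_acc` (m/s^2, >= g).
#' @export
banking_and_lift <- function(a_hat, omega, params = stork_params()) {
  if (a_hat <= 0) stop("a_hat must be positive")
  list(beta = atan(a_hat * omega / params$g_a),
       lift_acc = sqrt(params$g_a^2 + (a_hat * omega)^2))
}

#' Lift and drag coefficients, total drag and sink rate
#'
#' Standard glide-polar relations: `C_L = 2 L / (rho a^2 S)`, induced drag
#' `C_Di = K C_L^2 / (pi A_R)`, `C_D = C_Dni + C_Di`, total drag
#' `D = C_D rho a^2 S / 2`. Drag drains kinetic energy at rate `D a`; to
#' hold airspeed the bird converts potential energy, sinking relative to
#' the air at `a_z = D a / (m g)` (positive down).
#'
#' @inheritParams banking_and_lift
#' @param lift_acc lift per unit mass `L/m`, m/s^2.
#' @return List with `c_l`, `c_d`, `drag` (N) and `sink_rate` (m/s,
#'   positive down).
#' @export
drag_and_sink <- function(a_hat, lift_acc, params = stork_params()) {
  if (a_hat <= 0) stop("a_hat must be positive")
  lift <- params$mass * lift_acc
  q_s <- params$rho * a_hat^2 * params$s_wing  # 2 x dynamic pressure x area
  c_l <- 2 * lift / q_s
  c_d <- params$cd_ni + params$k_ind * c_l^2 / (pi * params$aspect_ratio)
  drag <- c_d * q_s / 2
  list(c_l = c_l, c_d = c_d, drag = drag,
       sink_rate = drag * a_hat / (params$mass * params$g_a))
}

#' Thermal strength from observed climb and aerodynamic sink
#'
#' The vertical air velocity is the climb observed over ground plus the
#' bird's sink relative to the air: `w_z = g_z + a_z`, positive upward.
#'
#' @param sink_rate sink rate relative to the air, m/s (positive down).
#' @param gz mean vertical ground speed, m/s (positive up).
#' @return Thermal strength, m/s (positive up).
#' @export
thermal_strength <- function(sink_rate, gz) gz + sink_rate

#' Height exchanged for an airspeed change
#'
#' Kinetic-potential energy exchange: accelerating from `a` to `a + delta_a`
#' at constant total energy costs `((a + delta_a)^2 - a^2) / (2 g)` metres
#' of height. Around 10 m/s, one m/s of airspeed is worth about one metre.
#'
#' @param a airspeed, m/s.
#' @param delta_a airspeed change, m/s.
#' @param g_a gravitational acceleration, m/s^2.
#' @return Height change, metres.
#' @export
height_for_speed_change <- function(a, delta_a, g_a = 9.81) {
  if (a <= 0) stop("a must be positive")
  ((a + delta_a)^2 - a^2) / (2 * g_a)
}

#' Full flight characteristics of a circling event
#'
#' Combines [vertical_ground_speed()], [circle_geometry()],
#' [banking_and_lift()], [drag_and_sink()] and [thermal_strength()] for one
#' detected event.
#'
#' @param event a `circling_event` from [classify_window()] /
#'   [detect_circling_events()].
#' @param params [stork_params()] aerodynamic parameters.
#' @return Named list: `gz`, `omega`, `radius`, `circle_time`, `beta`
#'   (radians), `beta_deg`, `lift_acc`, `c_l`, `c_d`, `drag`, `sink_rate`,
#'   `w_z`.
#' @export
flight_characteristics <- function(event, params = stork_params()) {
  est <- event$estimate
  vs <- event$window
  gz <- event$gz
  geo <- circle_geometry(vs, est$w, est$a_hat, vs$dt)
  bl <- banking_and_lift(est$a_hat, geo$omega, params)
  ds <- drag_and_sink(est$a_hat, bl$lift_acc, params)
  c(list(gz = gz), geo, bl,
    list(beta_deg = bl$beta * 180 / pi), ds,
    list(w_z = thermal_strength(ds$sink_rate, gz)))
}
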