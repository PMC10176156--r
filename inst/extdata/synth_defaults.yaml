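# Default parameterization of the synthetic cohort generator.
#
# All trajectory and noise defaults live here (not in code) so that the
# generating model for a run is documented in one place.  Ages ("d" below)
# are developmental ages in real-valued months: chronological age plus a
# per-subject offset (SD sigma_dev) plus a per-session situational offset
# (SD sigma_sess).
#
# Posture model: per-frame posture is drawn from softmax(z_p(d)) where each
# posture logit is logistic in d,
#     z_p(d) = base + amp / (1 + exp(-(d - mid)/scale)).
# The defaults reproduce the canonical gross-motor sequence: supine lying
# declines first, then prone, a transient crawl-posture peak around
# 10-13 months, then a persistent rise of sitting and (last) standing.
#
# Movement model: within a posture, the maturation level among
# still < proto < elementary < fluent follows a cumulative-logit (ordinal)
# model with latent maturity u = (d - onset)/rate and fixed increasing
# thresholds; pivot/roll/transition get small fixed probabilities in the
# postures where they occur, and the ordinal block is scaled to the
# remaining mass.

categories:
  postures: [supine, prone, side, crawl, sitting, standing]
  movements: [still, proto, elementary, fluent, pivot, roll, transition]

cohort:
  n_subjects: 61
  age_range_months: [4.0, 18.0]
  recordings_per_subject: [1, 7]      # discrete uniform
  session_hours_range: [1.4, 14.2]    # continuous uniform, mean 7.8 h
  playtime_fraction: 0.26
  carried_fraction: 0.10
  lowquality_fraction: 0.20
  sigma_dev: 1.0       # per-subject developmental offset SD (months)
  sigma_sess: 0.85     # per-session situational offset SD (months)
  p_stay: 0.9          # frame-to-frame state persistence
  block_minutes: 5.0        # mean length of carried/low-quality blocks
  play_block_minutes: 30.0  # mean length of free-play / other awake periods
  hop_seconds: 1.15    # frame hop; 1 h = 3130 frames

posture_trajectories:
  supine:   {base:  2.5, amp: -4.0, mid:  7.0, scale: 1.5}
  prone:    {base:  1.6, amp: -3.5, mid:  9.5, scale: 1.5}
  side:     {base:  0.0, amp: -1.5, mid:  9.0, scale: 2.0}
  crawl:    {base: -3.0, amp:  4.0, mid:  8.5, scale: 1.2}
  sitting:  {base: -3.0, amp:  4.5, mid:  9.0, scale: 1.5}
  standing: {base: -6.5, amp:  8.5, mid: 12.5, scale: 1.5}

movement_maturation:
  thresholds: {still: -1.0, proto: 1.0, elementary: 3.0}  # cumulative-logit cuts
  onset:  {supine: 2.0, prone: 5.0, side: 4.0, crawl: 8.0, sitting: 8.0, standing: 11.0}
  rate:   {supine: 1.5, prone: 1.5, side: 1.5, crawl: 1.5, sitting: 1.5, standing: 1.5}
  extras:                     # fixed movement probabilities outside the ordinal block
    supine:   {roll: 0.05, transition: 0.02}
    prone:    {pivot: 0.06, roll: 0.04, transition: 0.03}
    side:     {roll: 0.06, transition: 0.04}
    crawl:    {transition: 0.06}
    sitting:  {transition: 0.05}
    standing: {transition: 0.05}

# Emission model outside free play.  Non-playtime periods (feeding, quiet
# holding, restraint in a seat) are still-dominated and age-invariant, which
# is what makes 10-min windows discriminable for the playtime classifier.
nonplay_emission:
  posture:  {supine: 0.35, prone: 0.05, side: 0.15, crawl: 0.025, sitting: 0.40, standing: 0.025}
  movement: {still: 0.85, proto: 0.10, transition: 0.05}
carried_emission:
  posture:  {supine: 0.10, prone: 0.02, side: 0.08, crawl: 0.00, sitting: 0.70, standing: 0.10}
  movement: {still: 0.90, proto: 0.05, transition: 0.05}

# Physical growth median curves, exponential approach mu(t) = a + b*(1 - exp(-t/tau)),
# strictly increasing for b, tau > 0.  Units: cm / kg / cm; sigma_subj is the
# per-subject random intercept SD, sigma_meas the measurement-error SD.
physical_curves:
  length: {a: 50.0, b: 34.0, tau: 9.0, sigma_subj: 1.6,  sigma_meas: 0.40}
  weight: {a:  3.3, b:  8.5, tau: 9.0, sigma_subj: 0.55, sigma_meas: 0.12}
  hc:     {a: 36.0, b: 12.0, tau: 7.0, sigma_subj: 0.70, sigma_meas: 0.15}
physical_visits:
  schedule_months: [4, 5, 6, 8, 10, 12, 18]
  attend_prob: 0.85
  jitter_sd_months: 0.25
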