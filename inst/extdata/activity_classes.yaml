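# Activity archetypes for the synthetic motion generator.
#
# Each class gives a fundamental frequency (Hz) and a set of sinusoidal
# components. A component applies to the listed 0-based joint indices;
# amp_x / amp_y are oscillation amplitudes as fractions of body height,
# phase is in cycles (0..1). The hip centre (joint 0) is never listed:
# it is derived per frame as the femur-head midpoint.
#
# running: alternating arm/leg swing with vertical leg lift and a small
#   trunk bob, at a moderate stride rate.
# aerobics: slow, large, bilaterally synchronous arm and leg excursions
#   (jumping-jack-like) with strong vertical trunk motion.
# table_tennis: fast, right-arm-dominant strokes with lateral trunk sway
#   and nearly static legs.
classes:
  running:
    freq_hz: 1.4
    components:
      - {joints: [4, 5],   amp_x: 0.08, amp_y: 0.05, phase: 0.0}
      - {joints: [7, 8],   amp_x: 0.08, amp_y: 0.05, phase: 0.5}
      - {joints: [10, 11], amp_x: 0.07, amp_y: 0.10, phase: 0.5}
      - {joints: [13, 14], amp_x: 0.07, amp_y: 0.10, phase: 0.0}
      - {joints: [1, 2],   amp_x: 0.00, amp_y: 0.02, phase: 0.0}
  aerobics:
    freq_hz: 0.8
    components:
      - {joints: [4, 5],   amp_x: 0.13, amp_y: 0.15, phase: 0.0}
      - {joints: [7, 8],   amp_x: 0.13, amp_y: 0.15, phase: 0.0}
      - {joints: [10, 11], amp_x: 0.06, amp_y: 0.03, phase: 0.0}
      - {joints: [13, 14], amp_x: 0.06, amp_y: 0.03, phase: 0.0}
      - {joints: [1, 2],   amp_x: 0.00, amp_y: 0.06, phase: 0.25}
  table_tennis:
    freq_hz: 1.1
    components:
      - {joints: [7, 8],   amp_x: 0.13, amp_y: 0.08, phase: 0.0}
      - {joints: [4, 5],   amp_x: 0.02, amp_y: 0.01, phase: 0.5}
      - {joints: [10, 11], amp_x: 0.02, amp_y: 0.01, phase: 0.0}
      - {joints: [13, 14], amp_x: 0.02, amp_y: 0.01, phase: 0.5}
      - {joints: [1, 2],   amp_x: 0.03, amp_y: 0.01, phase: 0.25}
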