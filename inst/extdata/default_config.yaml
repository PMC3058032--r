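# Facility chemistry / plate / validation configuration.
# All numeric limits here are facility policy, not code constants.
chemistry:
  total_reaction_volume: 10.0   # uL per well
  mix_volume: 4.0               # uL pre-made reaction mix, every well
  fixed_template_volume: 1.0    # uL, FIXED dosing mode
  fixed_primer_volume: 1.0      # uL, FIXED dosing mode
  target_template_mass:         # ng per reaction, by sequencing type
    standard: 100.0
    long_read: 150.0
  target_primer_amount: 5.0     # pmol per reaction
  pipetting_increment: 0.1      # uL, recipes rounded half-up to this
plate:
  rows: 8
  cols: 12
  traversal: column             # column (A1,B1..H1,A2..) or row
  reaction_controls: 1
  instrument_controls: 1
  control_placement: plate_tail # plate_tail or after_samples
manual:
  volume_multiplier: 2.0        # manual pipetting uses larger volumes
robot:
  volume_decimals: 1
confirmation:
  safety_factor: 1.5            # head room over summed per-reaction demand
  supply_increment: 0.5         # uL, customer supply volumes round up to this
limits:
  template_concentration: { min: 20.0, max: 200.0 }   # ng/uL
  min_template_volume: 10.0                           # uL
  primer_concentration: { min: 1.0, max: 100.0 }      # pmol/uL
  min_primer_volume: 10.0                             # uL
  max_requested_read_length: 1100                     # bases
sequencing_types:
  standard:  { default_read_length: 700 }
  long_read: { default_read_length: 900 }
facility_primers: [T7, T7term, M13F, M13R, SP6]
run_series: A
pagination: 20
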