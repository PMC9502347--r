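# Condition presets for the canonical synthetic study design.
#
# version: 1
#
# Two layers of multiplicative factors on the base generator parameters:
#
#   surrogates:  dye-physics factors that apply to EVERY condition of that
#                surrogate, including its untreated control (section 1).
#                The hydrophilic dye penetrates deep (large decay length,
#                transdermal in untreated skin); the lipophilic dye stops in
#                the viable epidermis of untreated skin.
#
#   conditions:  treatment modifiers relative to the control of the same
#                (surrogate, timepoint) stratum. Controls carry none.
#                "during" time points reduce the deposited amount (part of
#                the formulation is lost to the towel mask, and massage rubs
#                more of it away); "after + massage" increases amount and
#                depth scale for the lipophilic dye (the massage removes the
#                water front on top of the skin); "after, no massage"
#                reduces them for the lipophilic dye (the water front keeps
#                the oil-dissolved dye out). Massage raises the hydration
#                index, a treatment without massage leaves the skin drier at
#                the end of the experiment.

version: 1

surrogates:
  hydrophilic:
    dye_decay_um: 4.5
  lipophilic:
    dye_decay_um: 2.9

conditions:
  # ---- hydrophilic, during -------------------------------------------------
  - {skin_section: 1, surrogate: hydrophilic, timepoint: during}
  - skin_section: 2
    surrogate: hydrophilic
    timepoint: during
    modifiers: {dye_amount: 0.80}
  - skin_section: 3
    surrogate: hydrophilic
    timepoint: during
    modifiers: {dye_amount: 0.54, hydration_index: 1.6}
  # ---- lipophilic, during --------------------------------------------------
  - {skin_section: 1, surrogate: lipophilic, timepoint: during}
  - skin_section: 2
    surrogate: lipophilic
    timepoint: during
    modifiers: {dye_amount: 0.66}
  - skin_section: 3
    surrogate: lipophilic
    timepoint: during
    modifiers: {dye_amount: 0.32, hydration_index: 1.6}
  # ---- hydrophilic, after --------------------------------------------------
  - {skin_section: 1, surrogate: hydrophilic, timepoint: after}
  - skin_section: 2
    surrogate: hydrophilic
    timepoint: after
    modifiers: {dye_amount: 1.15, hydration_index: 0.8}
  - skin_section: 3
    surrogate: hydrophilic
    timepoint: after
    modifiers: {dye_amount: 1.25, hydration_index: 1.4}
  # ---- lipophilic, after ---------------------------------------------------
  - {skin_section: 1, surrogate: lipophilic, timepoint: after}
  - skin_section: 2
    surrogate: lipophilic
    timepoint: after
    modifiers: {dye_amount: 0.60, dye_decay_um: 0.25, hydration_index: 0.8}
  - skin_section: 3
    surrogate: lipophilic
    timepoint: after
    modifiers: {dye_amount: 1.40, dye_decay_um: 1.20, hydration_index: 1.4}
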