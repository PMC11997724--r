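# Default code dictionaries for the phenotyping rules. Site deployments
# should replace the medication lists with their own formulary mapping.
anxiety_dx_prefixes: [F40, F41]
anxiolytic_meds: [lorazepam, alprazolam, clonazepam, diazepam, buspirone,
                  hydroxyzine]
psych_dx_prefixes: [F]
depression_dx_prefixes: [F32, F33]
antidepressant_meds: [sertraline, fluoxetine, citalopram, escitalopram,
                      paroxetine, venlafaxine, duloxetine, bupropion,
                      mirtazapine, amitriptyline]
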