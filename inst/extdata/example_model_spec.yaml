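outcome: outcome
missing_partner_policy: dummy
blocks:
- name: distance_problem
  kind: binary
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  partner: no
- name: mother_edu
  kind: categorical
  levels:
  - none
  - primary_inc
  - primary_comp
  - secondary_plus
  reference: none
  partner: no
- name: partner_edu
  kind: categorical
  levels:
  - none
  - primary_inc
  - primary_comp
  - secondary_plus
  reference: none
  partner: yes
- name: watches_tv
  kind: binary
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  partner: no
- name: birth_order
  kind: categorical
  levels:
  - first
  - two_four
  - five_plus
  reference: first
  partner: no
- name: religion
  kind: categorical
  levels:
  - catholic
  - protestant
  - islam
  - other
  reference: catholic
  partner: no
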