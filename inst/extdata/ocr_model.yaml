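arrival:
  base_rate: 0.402739726027397
  scale_factor: 1.0
subprocesses:
  Initial Preparation:
    name: Initial Preparation
    capacity: 9.0
    activities:
    - name: OCR sends documents
      family: uniform
      params:
      - 0.5
      - 1.0
    - name: P&L reviews
      family: triangular
      params:
      - 1.0
      - 8.0
      - 21.0
    - name: PI prepares documents
      family: triangular
      params:
      - 1.0
      - 2.0
      - 3.0
    - name: P&L reviews (2nd)
      family: uniform
      params:
      - 0.5
      - 1.0
  Contract Negotiation:
    name: Contract Negotiation
    capacity: 12.0
    duration:
      family: exponential
      params: 28.5
  Budget Negotiation:
    name: Budget Negotiation
    capacity: 11.0
    duration:
      family: exponential
      params: 25.0
  PI Approval:
    name: PI Approval
    capacity: 5.0
    duration:
      family: lognormal
      params:
      - 5.0
      - 8.300000000000001
  DSR Approval:
    name: DSR Approval
    capacity: 3.0
    duration:
      family: lognormal
      params:
      - 2.5
      - 2.8
  Sponsor Approval:
    name: Sponsor Approval
    capacity: 7.0
    duration:
      family: lognormal
      params:
      - 6.5
      - 15.9
routing:
- - Initial Preparation
  - Contract Negotiation
- - Initial Preparation
  - Budget Negotiation
- - Contract Negotiation
  - PI Approval
- - Budget Negotiation
  - PI Approval
- - PI Approval
  - DSR Approval
- - DSR Approval
  - Sponsor Approval
branch_traversal:
  Initial Preparation: 1.0
  Contract Negotiation: 1.0
  Budget Negotiation: 1.0
  PI Approval: 1.0
  DSR Approval: 1.0
  Sponsor Approval: 1.0
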