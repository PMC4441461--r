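goal: Choose best add-on therapy to metformin
context: >-
  Add-on pharmacotherapy to metformin for adults with type 2 diabetes;
  objectives limited to outcomes with comparative evidence.
objectives:
  - name: Maximizing benefits
    children:
      - Reduce HbA1c
  - name: Minimizing harms
    children:
      - name: Minimizing non-serious harms
        children:
          - Risk of fracture
          - Weight gain
          - GI symptoms
      - name: Minimizing serious harms
        children:
          - Severe hypoglycemia
          - CHF risk
          - Acute pancreatitis
          - Risk of bladder cancer
alternatives:
  - Metformin
  - Exenatide
  - Sitagliptin
  - Sulfonylureas
  - Pioglitazone
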