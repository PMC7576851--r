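case_id,group,age,sex,pmd,staging
H169,normal,81,male,24,A2 B0 C1 (none)
H180,normal,73,male,33,A2 B0 C1 (none)
H187,normal,98,female,15,A2 B2 C1 (intermediate)
H191,normal,77,male,25,A0 B0 C0 (none)
H196,normal,85,male,15,A1 B0 C0 (none)
H229,normal,88,female,17,A2 B1 C2 (low)
H243,normal,77,female,13,A0 B0 C0 (none)
H246,normal,89,male,17,A0 B1 C0 (none)
AZ99,AD,94,female,8.5,A3 B3 C2 (high)
AZ102,AD,84,female,14.5,A3 B2 C2 (intermediate)
AZ107,AD,86,male,NA,A2 B3 C1 (intermediate)
AZ108,AD,94,female,11.5,A3 B3 C2 (high)
AZ109,AD,90,female,31,A3 B2 C1 (intermediate)
AZ110,AD,86,female,15,A3 B3 C2 (high)
AZ113,AD,77,male,3.5,A3 B3 C2 (high)
AZ119,AD,89,male,5,A3 B2 C2 (intermediate)
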