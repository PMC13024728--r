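group,side,label,distance_px
patient,left,L0,47
patient,left,L1,34
patient,left,L2,24
patient,left,L3,17
patient,left,L4,19
patient,left,L5,29
patient,left,L6,43
patient,left,L7,35
patient,left,L8,19
patient,left,L9,11
patient,left,L10,18
patient,left,L11,32
patient,right,R0,51
patient,right,R1,38
patient,right,R2,26
patient,right,R3,18
patient,right,R4,18
patient,right,R5,24
patient,right,R6,33
patient,right,R7,26
patient,right,R8,14
patient,right,R9,10
patient,right,R10,19
patient,right,R11,33
normal,left,L0,39
normal,left,L1,24
normal,left,L2,12
normal,left,L3,5.0
normal,left,L4,11
normal,left,L5,24
normal,left,L6,41
normal,left,L7,37
normal,left,L8,20
normal,left,L9,7.0
normal,left,L10,9
normal,left,L11,23
normal,right,R0,49
normal,right,R1,34
normal,right,R2,20
normal,right,R3,12
normal,right,R4,15
normal,right,R5,27
normal,right,R6,40
normal,right,R7,35
normal,right,R8,19
normal,right,R9,9
normal,right,R10,15
normal,right,R11,31
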