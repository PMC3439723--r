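Patient_place0 = (beta, 1).Patient_place1;
Patient_place1 = (alpha, 3).Patient_place0;
Wait_room0_idle = (beta, 1).Wait_room0_busy;
Wait_room0_busy = (gamma, 1000).Wait_room0_idle;
Resource_place1_idle = (gamma, 1000).Resource_place1_busy;
Resource_place1_busy = (alpha, 3).Resource_place1_idle;
Patient_place0[2] <beta, alpha> (Wait_room0_idle[2] <gamma> Resource_place1_idle[1]);
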